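#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods
#'
#' `tidy()` on an [exchange_test()] returns its one-row summary;
#' `glance()` adds nothing beyond the same row (the object has a single
#' statistic) and exists for broom-style pipelines. On an
#' `exchange_report`, `tidy()` returns the full test table and `glance()`
#' a one-row overview.
#'
#' @param x An `exchange_test` or `exchange_report`.
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' null <- free_selection_null(rep(1, 8))
#' tidy(free_selection_test(null, 7))
#' glance(run_replication())
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy exchange_test
#' @export
tidy.exchange_test <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed, n = x$n,
         null = x$null, p_value = x$p_value, method = x$method,
         n_sims = x$n_sims, seed = x$seed)
}

#' @rdname tidiers
#' @method glance exchange_test
#' @export
glance.exchange_test <- function(x, ...) {
  tidy(x)
}

#' @rdname tidiers
#' @method tidy exchange_report
#' @export
tidy.exchange_report <- function(x, ...) {
  x$tests
}

#' @rdname tidiers
#' @method glance exchange_report
#' @export
glance.exchange_report <- function(x, ...) {
  tibble(n_subjects = length(unique(x$counts$subject)),
         n_tests = nrow(x$tests),
         n_flags = nrow(x$notes),
         method = x$config$method,
         seed = x$config$seed)
}
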