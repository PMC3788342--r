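#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a free-selection null distribution
#'
#' Draws the exact Poisson-binomial probability mass of the number of target
#' retrievals under the conditioned chance model, optionally marking an
#' observed count so the upper-tail p-value can be read off the shaded bars.
#'
#' @param object A [free_selection_null()].
#' @param observed Optional observed retrieval count to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' null <- free_selection_null(c(4, 2, 1, 1, 1, 1, 1, 2, 1, 2, 1, 1))
#' autoplot(null, observed = 7)
#' @method autoplot free_selection_null
#' @export
autoplot.free_selection_null <- function(object, observed = NULL, ...) {
  df <- tibble(count = 0:length(object$k),
               probability = pb_density(object$inclusion_probs))
  df$in_tail <- if (is.null(observed)) FALSE else df$count >= observed
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$count,
                                        y = .data$probability,
                                        fill = .data$in_tail)) +
    ggplot2::geom_col(show.legend = !is.null(observed)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65",
                                          `TRUE` = "firebrick"),
                               name = "in upper tail") +
    ggplot2::labs(x = "target retrievals", y = "null probability",
                  title = "Free-selection chance model",
                  subtitle = sprintf("k-profile: %s (m = %d)",
                                     paste(object$k, collapse = " "),
                                     object$m)) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed - 0.5,
                                 linetype = "dashed")
  }
  p
}

#' Plot the p-values of a replication report
#'
#' One point per test on a log p-value scale, faceted by experiment, with
#' the conventional 0.05 and 0.001 reference levels.
#'
#' @param object An `exchange_report` from [run_replication()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot exchange_report
#' @export
autoplot.exchange_report <- function(object, ...) {
  df <- object$tests[!is.na(object$tests$p_value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_value, y = .data$subject,
                                   shape = .data$statistic)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_vline(xintercept = c(0.05, 0.001), linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$experiment), ncol = 1) +
    ggplot2::labs(x = "one-tailed p-value (log scale)", y = NULL,
                  title = "Deferred-exchange replication") +
    ggplot2::theme_minimal()
}
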