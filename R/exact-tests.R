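#' Exact upper tail of the binomial distribution
#'
#' Computes `P(X >= x)` for `X ~ Binomial(n, prob)` by direct summation of
#' the probability mass over `x..n`. This is the one-tailed "above chance"
#' test used throughout the forced-selection and complete-sequence analyses;
#' with four equally available items the conventional chance level is 1/4.
#'
#' @param x Observed number of successes (vectorised).
#' @param n Number of trials.
#' @param prob Per-trial success probability.
#' @return `P(X >= x)`, a numeric vector.
#' @examples
#' binom_upper_tail(9, 13, 0.25)   # 9.89e-4
#' binom_upper_tail(0, 13, 0.25)   # 1: the whole support
#' @export
binom_upper_tail <- function(x, n, prob = 0.25) {
  m <- max(length(x), length(n), length(prob))
  x <- rep_len(x, m)
  n <- rep_len(n, m)
  prob <- rep_len(prob, m)
  if (any(is.na(x) | is.na(n) | is.na(prob))) {
    abort("binom_upper_tail() requires non-missing arguments.")
  }
  if (any(n != round(n) | x != round(x))) abort("x and n must be integers.")
  if (any(x < 0 | x > n)) abort("x must satisfy 0 <= x <= n.")
  if (any(prob < 0 | prob > 1)) abort("prob must lie in [0, 1].")
  vapply(seq_len(m), function(i) {
    sum(dbinom(seq.int(x[i], n[i]), n[i], prob[i]))
  }, numeric(1))
}

#' Construct an exchange-test result
#'
#' The common container for every hypothesis test in the package: an observed
#' count, its denominator, a description of the null, the one-tailed p-value,
#' and how it was computed (exactly, or by seeded Monte Carlo).
#'
#' @param statistic Name of the statistic tested (e.g.
#'   `"correct_selections"`).
#' @param observed Observed count.
#' @param n Denominator (number of trials).
#' @param null Text description of the null model.
#' @param p_value One-tailed p-value, the probability of a count at least as
#'   large under the null.
#' @param method `"exact"` or `"monte_carlo"`.
#' @param n_sims,seed Monte Carlo replicate count and seed (`NA` for exact).
#' @return An object of class `exchange_test`.
#' @export
exchange_test <- function(statistic, observed, n, null, p_value,
                          method = c("exact", "monte_carlo"),
                          n_sims = NA_integer_, seed = NA_integer_) {
  method <- match.arg(method)
  stopifnot(observed >= 0, observed <= n, p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(statistic = statistic, observed = as.integer(observed),
         n = as.integer(n), null = null, p_value = min(p_value, 1),
         method = method, n_sims = as.integer(n_sims),
         seed = as.integer(seed)),
    class = "exchange_test")
}

#' @export
print.exchange_test <- function(x, ...) {
  cat(sprintf("Exchange test: %s\n", x$statistic))
  cat(sprintf("  observed %d of %d;  null: %s\n", x$observed, x$n, x$null))
  cat(sprintf("  one-tailed p = %s  (%s%s)\n", format_p(x$p_value), x$method,
              if (x$method == "monte_carlo")
                sprintf(", %d replicates, seed %d", x$n_sims, x$seed) else ""))
  invisible(x)
}

#' Format a p-value at reporting granularity
#'
#' Three decimals, with values below 0.001 shown as `"<0.001"`.
#' @param p Numeric p-values.
#' @return Character vector.
#' @examples
#' format_p(c(0.09362793, 5.96e-8))
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

#' Exact binomial tests for forced-selection counts
#'
#' `selection_test_forced()` tests whether the number of correct selections
#' exceeds chance; `complete_sequence_test()` tests the number of complete
#' behavioural sequences (select the target, transport it, exchange it)
#' against the conservative assumption that a full sequence succeeds by
#' chance with probability `chance` per trial. Both use the exact binomial
#' upper tail with the *full* trial count as denominator — refusal trials are
#' failures, not exclusions.
#'
#' `exchange_proportion()` reports exchange accuracy among trials where the
#' target was available. The published analyses report this as a proportion;
#' a binomial tail at the same chance level can be attached with
#' `test = TRUE`, but its null is a matter of interpretation (chance refers
#' to the selection stage) and it is off by default.
#'
#' @param counts A row (or rows) of observed counts from [score_forced()] or
#'   [score_free()].
#' @param chance Per-trial success probability under the null; 1/4 for four
#'   equally available items.
#' @param test Attach a binomial tail to the exchange proportion?
#' @return A tibble with one row per input row: identifiers, `statistic`,
#'   `observed`, `n`, `p_value` (and `proportion` for
#'   `exchange_proportion()`), plus `method`.
#' @examples
#' scores <- score_forced(ape_exchange_trials("forced"))
#' selection_test_forced(dplyr::filter(scores, experiment == "exp1"))
#' @export
selection_test_forced <- function(counts, chance = 0.25) {
  run_count_test(counts, "correct_selections", "n_correct_selections", chance)
}

#' @rdname selection_test_forced
#' @export
complete_sequence_test <- function(counts, chance = 0.25) {
  run_count_test(counts, "complete_sequences", "n_complete_sequences", chance)
}

run_count_test <- function(counts, statistic, column, chance) {
  counts <- as_tibble(counts)
  if (nrow(counts) == 0 || any(counts$n_trials == 0)) {
    abort("Observed counts must cover at least one trial.")
  }
  ids <- intersect(c("subject", "species", "experiment"), names(counts))
  res <- purrr::pmap_dfr(counts, function(...) {
    row <- list(...)
    obs <- row[[column]]
    p <- if (is.na(obs)) NA_real_ else binom_upper_tail(obs, row$n_trials, chance)
    tibble(statistic = statistic, observed = obs, n = row$n_trials,
           null = sprintf("Binomial(n, %.4g) upper tail", chance),
           p_value = p, method = "exact")
  })
  dplyr::bind_cols(counts[ids], res)
}

#' @rdname selection_test_forced
#' @export
exchange_proportion <- function(counts, chance = 0.25, test = FALSE) {
  counts <- as_tibble(counts)
  ids <- intersect(c("subject", "species", "experiment"), names(counts))
  res <- purrr::pmap_dfr(counts, function(...) {
    row <- list(...)
    avail <- row$n_target_available
    obs <- row$n_correct_exchanges
    prop <- if (is.na(obs) || avail == 0) NA_real_ else obs / avail
    p <- if (test && !is.na(obs) && avail > 0) {
      binom_upper_tail(obs, avail, chance)
    } else {
      NA_real_
    }
    tibble(statistic = "correct_exchanges", observed = obs, n = avail,
           proportion = prop, p_value = p,
           method = if (test) "exact" else NA_character_)
  })
  dplyr::bind_cols(counts[ids], res)
}
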