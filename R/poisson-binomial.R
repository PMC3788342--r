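#' Poisson-binomial distribution by iterative convolution
#'
#' The number of trials on which the target is retrieved under the
#' free-selection null is a sum of independent Bernoulli variables with
#' *unequal* success probabilities (one per trial, `k_t / m`), i.e. a
#' Poisson-binomial variable. `pb_density()` computes its full probability
#' mass function by dynamic programming over counts: starting from the empty
#' product, each trial's Bernoulli is convolved in, so after trial `t` the
#' vector holds the exact distribution of successes among the first `t`
#' trials. `pb_upper_tail()` sums the mass at and above a threshold.
#'
#' Runtime is O(n^2) additions for n trials and the result is exact to
#' floating-point rounding (well below 1e-12 for the trial counts that occur
#' in this design).
#'
#' @param probs Numeric vector of per-trial success probabilities in
#'   \[0, 1\].
#' @param x Threshold count, `0 <= x <= length(probs)`.
#' @return `pb_density()`: numeric vector of length `length(probs) + 1`,
#'   entry `i` holding `P(X = i - 1)`. `pb_upper_tail()`: `P(X >= x)`.
#' @examples
#' pb_upper_tail(rep(0.25, 12), 7)        # equals binom_upper_tail(7, 12, 0.25)
#' pb_upper_tail(c(1, 0.5, 0.25), 3)      # 0.125: all three must succeed
#' @export
pb_density <- function(probs) {
  probs <- as.numeric(probs)
  if (length(probs) && (anyNA(probs) || any(probs < 0 | probs > 1))) {
    abort("All probabilities must lie in [0, 1].")
  }
  f <- 1
  for (p in probs) {
    f <- c(f * (1 - p), 0) + c(0, f * p)
  }
  f
}

#' @rdname pb_density
#' @export
pb_upper_tail <- function(probs, x) {
  n <- length(probs)
  if (length(x) != 1 || is.na(x) || x != round(x) || x < 0 || x > n) {
    abort("x must be a single integer with 0 <= x <= length(probs).")
  }
  f <- pb_density(probs)
  sum(f[seq.int(x + 1, n + 1)])
}
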