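#' The free-selection chance model
#'
#' In the free multi-item design a subject may carry any subset of the `m`
#' items out of the compartment, so a fixed-probability binomial test does
#' not apply. The chance model instead *conditions on the observed per-trial
#' removal counts* (the k-profile): under the null, on a trial where the
#' subject removed `k_t` items, those `k_t` items are a uniform draw without
#' replacement from the `m` available, so the target is included with
#' probability `k_t / m` independently across trials. The number of
#' target retrievals is then Poisson-binomial with those inclusion
#' probabilities.
#'
#' @param k Integer vector of per-trial removal counts (see [k_profile()]);
#'   each must satisfy `1 <= k <= m`.
#' @param m Item universe size (4 in the bundled experiments).
#' @return An object of class `free_selection_null` with elements `k`, `m`
#'   and `inclusion_probs` (`k/m`).
#' @examples
#' free_selection_null(c(4, 2, 1, 1, 1, 1, 1, 2, 1, 2, 1, 1))
#' @export
free_selection_null <- function(k, m = 4) {
  k <- as.integer(k)
  if (length(m) != 1 || is.na(m) || m < 2 || m != round(m)) {
    abort("m must be a single integer >= 2.")
  }
  if (anyNA(k) || any(k < 1 | k > m)) {
    abort("Every removal count must satisfy 1 <= k <= m.")
  }
  structure(list(k = k, m = as.integer(m), inclusion_probs = k / m),
            class = "free_selection_null")
}

#' @export
print.free_selection_null <- function(x, ...) {
  cat(sprintf("Free-selection null: %d trials, %d items\n", length(x$k), x$m))
  cat("  k-profile:", paste(x$k, collapse = " "), "\n")
  invisible(x)
}

#' Simulate target retrievals under the free-selection null
#'
#' The single-replicate primitive behind the Monte Carlo tests: for each
#' trial, `k_t` of the `m` items are drawn uniformly without replacement and
#' the draw is checked for the target. Because the draw is uniform, the
#' target's inclusion indicator is Bernoulli(`k_t / m`), which is how it is
#' simulated.
#'
#' @param null A [free_selection_null()].
#' @param n_reps Number of replicates.
#' @param seed Integer seed; the stream is local and does not disturb the
#'   caller's RNG state.
#' @return `simulate_free_selection()`: a logical matrix of dimension
#'   `n_reps x n_trials`, `TRUE` where the replicate's draw included the
#'   target. `simulate_retrieval_counts()`: integer vector of per-replicate
#'   retrieval totals.
#' @examples
#' null <- free_selection_null(c(1, 1, 2, 4))
#' colMeans(simulate_free_selection(null, 2000, seed = 1))  # ~ k/4
#' @export
simulate_free_selection <- function(null, n_reps = 1, seed) {
  stopifnot(inherits(null, "free_selection_null"))
  n <- length(null$k)
  withr::local_seed(seed)
  matrix(runif(n_reps * n) < rep(null$inclusion_probs, each = n_reps),
         nrow = n_reps, ncol = n)
}

#' @rdname simulate_free_selection
#' @export
simulate_retrieval_counts <- function(null, n_reps, seed) {
  counts <- rowSums(simulate_free_selection(null, n_reps, seed))
  as.integer(counts)
}

#' Free-selection test: did the subject retrieve the target above chance?
#'
#' Computes the probability of retrieving the target on at least `observed`
#' of the profiled trials under the conditioned chance model. The exact
#' method evaluates the Poisson-binomial upper tail by convolution
#' ([pb_upper_tail()]); the Monte Carlo method replays the null agent
#' `n_sims` times (default 50,000) and reports the plain proportion of
#' replicates with a retrieval count at least as large (optionally the
#' add-one estimator `(b + 1) / (n_sims + 1)`).
#'
#' @param null A [free_selection_null()].
#' @param observed Observed number of target retrievals.
#' @param method `"exact"` (default) or `"monte_carlo"`.
#' @param n_sims Monte Carlo replicates.
#' @param seed Integer seed (required for the Monte Carlo method).
#' @param estimator `"plain"` proportion (default) or `"add_one"`.
#' @return An [exchange_test()] object.
#' @examples
#' null <- free_selection_null(c(4, 2, 1, 1, 1, 1, 1, 2, 1, 2, 1, 1))
#' free_selection_test(null, observed = 7)                # exact: 0.0936
#' free_selection_test(null, 7, method = "monte_carlo",
#'                     n_sims = 5000, seed = 7)
#' @export
free_selection_test <- function(null, observed,
                                method = c("exact", "monte_carlo"),
                                n_sims = 50000, seed = NULL,
                                estimator = c("plain", "add_one")) {
  stopifnot(inherits(null, "free_selection_null"))
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  n <- length(null$k)
  if (observed < 0 || observed > n) {
    abort("observed must lie between 0 and the number of profiled trials.")
  }
  desc <- sprintf("uniform draw of k_t of %d items per trial (Poisson-binomial)",
                  null$m)
  if (method == "exact") {
    p <- pb_upper_tail(null$inclusion_probs, observed)
    return(exchange_test("target_retrievals", observed, n, desc, p, "exact"))
  }
  if (is.null(seed)) abort("The Monte Carlo method requires a seed.")
  counts <- simulate_retrieval_counts(null, n_sims, seed)
  hits <- sum(counts >= observed)
  p <- if (estimator == "plain") hits / n_sims else (hits + 1) / (n_sims + 1)
  exchange_test("target_retrievals", observed, n, desc, p, "monte_carlo",
                n_sims = n_sims, seed = seed)
}

#' Joint selection-and-exchange test ("correct behaviour")
#'
#' Extends the free-selection null with an exchange stage, to test the joint
#' event of both selecting and trading correctly. A trial counts as a
#' *correct behaviour* when the target was exchanged, or when nothing was
#' offered on a trial where the target had not been selected. The null agent
#' removes `k_t` uniformly drawn items and then offers exactly one of them,
#' chosen uniformly (the `"always_offer"` policy): the offer is the target
#' with probability `(k_t / m) * (1 / k_t) = 1 / m`, and a refusal never
#' occurs, so a null trial is correct with probability exactly `1 / m` and
#' the exact tail is `Binomial(n, 1/m)`. The alternative
#' `"offer_or_refuse"` policy lets the agent choose uniformly among the
#' `k_t` drawn items *or* refusing (`k_t + 1` options), under which a trial
#' can also be correct by refusing without the target; its per-trial correct
#' probability simplifies to `1 / (k_t + 1)` and the exact tail is the
#' corresponding Poisson-binomial.
#'
#' @inheritParams free_selection_test
#' @param observed_correct Observed number of correct behaviours among the
#'   profiled trials.
#' @param offer_policy Null agent's exchange behaviour; `"always_offer"` is
#'   the default chance agent.
#' @return An [exchange_test()] object.
#' @examples
#' null <- free_selection_null(rep(1, 8))
#' joint_behavior_test(null, observed_correct = 7)   # 3.8e-4
#' @export
joint_behavior_test <- function(null, observed_correct,
                                method = c("exact", "monte_carlo"),
                                offer_policy = c("always_offer",
                                                 "offer_or_refuse"),
                                n_sims = 50000, seed = NULL,
                                estimator = c("plain", "add_one")) {
  stopifnot(inherits(null, "free_selection_null"))
  method <- match.arg(method)
  offer_policy <- match.arg(offer_policy)
  estimator <- match.arg(estimator)
  n <- length(null$k)
  if (observed_correct < 0 || observed_correct > n) {
    abort("observed_correct must lie between 0 and the number of profiled trials.")
  }
  probs <- joint_trial_probs(null, offer_policy)
  desc <- sprintf("random removal then %s (per-trial correct prob %s)",
                  gsub("_", " ", offer_policy),
                  paste(signif(unique(probs), 3), collapse = "/"))
  if (method == "exact") {
    p <- pb_upper_tail(probs, observed_correct)
    return(exchange_test("correct_behaviors", observed_correct, n, desc, p,
                         "exact"))
  }
  if (is.null(seed)) abort("The Monte Carlo method requires a seed.")
  withr::local_seed(seed)
  correct <- simulate_joint_correct(null, offer_policy, n_sims)
  hits <- sum(correct >= observed_correct)
  p <- if (estimator == "plain") hits / n_sims else (hits + 1) / (n_sims + 1)
  exchange_test("correct_behaviors", observed_correct, n, desc, p,
                "monte_carlo", n_sims = n_sims, seed = seed)
}

joint_trial_probs <- function(null, offer_policy) {
  k <- null$k
  m <- null$m
  if (offer_policy == "always_offer") {
    ## inclusion (k/m) times uniform offer among k drawn items (1/k)
    rep(1 / m, length(k))
  } else {
    ## correct = offered target, or refused while not holding the target
    (k / m) / (k + 1) + (1 - k / m) / (k + 1)
  }
}

## Simulate per-replicate correct-behaviour counts by replaying the null
## agent replicate-by-trial: an inclusion draw (was the target among the k_t
## removed items?) followed by the offer stage. Under a uniform removal the
## target occupies any offer slot with equal probability, so both stages
## reduce to uniforms and the whole grid vectorises.
simulate_joint_correct <- function(null, offer_policy, n_sims) {
  k <- null$k
  m <- null$m
  n <- length(k)
  inc <- matrix(runif(n_sims * n) < rep(k / m, each = n_sims),
                nrow = n_sims, ncol = n)
  v <- matrix(runif(n_sims * n), nrow = n_sims, ncol = n)
  correct <- if (offer_policy == "always_offer") {
    ## given inclusion the target is one of k_t equally likely offers
    inc & v < matrix(rep(1 / k, each = n_sims), nrow = n_sims)
  } else {
    cut1 <- matrix(rep(1 / (k + 1), each = n_sims), nrow = n_sims)
    (inc & v >= cut1 & v < 2 * cut1) | (!inc & v < cut1)
  }
  as.integer(rowSums(correct))
}
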