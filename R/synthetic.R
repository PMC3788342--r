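#' Generative parameters for a synthetic exchange subject
#'
#' Describes a simulated ape well enough to generate trial tables for either
#' design: how strongly it prefers each item, how often it refuses to select
#' (forced design) or to enter the compartment (free design), how many items
#' it removes per free trial, and its exchange policy.
#'
#' @param preference_weights Named non-negative weights, one per item in
#'   `items`; selection probability is proportional to weight (free-design
#'   removals use successive draws proportional to the remaining weights).
#' @param refusal_prob Probability of refusing a forced selection or of not
#'   entering the compartment.
#' @param k_distribution Probability vector over removal counts `1..m` for
#'   the free design; defaults to always removing one item.
#' @param exchange_fidelity Probability of offering the target at the
#'   exchange when it was selected.
#' @param spurious_offer_prob Probability of offering a non-target object
#'   when the target was not selected.
#' @param items Item universe.
#' @return An object of class `subject_params`.
#' @examples
#' subject_params()                                   # uniform chance subject
#' subject_params(c(metal = 1, rope = 0, wood = 0, jute = 0),
#'                exchange_fidelity = 1)              # deterministic expert
#' @export
subject_params <- function(preference_weights = NULL, refusal_prob = 0,
                           k_distribution = NULL, exchange_fidelity = 1,
                           spurious_offer_prob = 0, items = item_universe()) {
  m <- n_items(items)
  if (is.null(preference_weights)) {
    preference_weights <- setNames(rep(1, m), items$item)
  }
  if (is.null(names(preference_weights)) ||
      !setequal(names(preference_weights), items$item)) {
    abort("preference_weights must be named with exactly the item labels.")
  }
  preference_weights <- preference_weights[items$item]
  if (anyNA(preference_weights) || any(preference_weights < 0) ||
      sum(preference_weights) <= 0) {
    abort("preference_weights must be non-negative with a positive sum.")
  }
  if (is.null(k_distribution)) {
    k_distribution <- c(1, rep(0, m - 1))
  }
  if (length(k_distribution) != m || anyNA(k_distribution) ||
      any(k_distribution < 0) || abs(sum(k_distribution) - 1) > 1e-9) {
    abort(sprintf("k_distribution must be %d probabilities summing to 1.", m))
  }
  for (p in c(refusal_prob, exchange_fidelity, spurious_offer_prob)) {
    if (is.na(p) || p < 0 || p > 1) {
      abort("All probability parameters must lie in [0, 1].")
    }
  }
  structure(list(preference_weights = preference_weights,
                 refusal_prob = refusal_prob,
                 k_distribution = k_distribution,
                 exchange_fidelity = exchange_fidelity,
                 spurious_offer_prob = spurious_offer_prob,
                 items = items),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat("Synthetic subject parameters\n")
  cat("  weights:", paste(sprintf("%s=%g", names(x$preference_weights),
                                  x$preference_weights), collapse = " "), "\n")
  cat(sprintf("  refusal %.3g; fidelity %.3g; spurious offer %.3g\n",
              x$refusal_prob, x$exchange_fidelity, x$spurious_offer_prob))
  cat("  k-distribution:", paste(signif(x$k_distribution, 3), collapse = " "),
      "\n")
  invisible(x)
}

## one weighted draw without replacement, successive selection
draw_without_replacement <- function(labels, weights, k) {
  out <- character(k)
  for (i in seq_len(k)) {
    j <- sample.int(length(labels), 1, prob = weights)
    out[i] <- labels[j]
    labels <- labels[-j]
    weights <- weights[-j]
  }
  out
}

#' Simulate a synthetic subject's trial table
#'
#' Generates a trial table in the package's forced or free schema from a
#' [subject_params()] specification. Forced design: each non-refused trial
#' selects one item with probability proportional to the preference weights,
#' and the exchange outcome follows `exchange_fidelity` /
#' `spurious_offer_prob`. Free design: each entered trial draws a removal
#' count from `k_distribution`, removes that many items by successive
#' weighted draws without replacement (first draw recorded as the first
#' touch), and the exchange stage applies as above. Deterministic given
#' `seed`.
#'
#' @param params A [subject_params()].
#' @param design `"forced"` or `"free"`.
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed.
#' @param subject,species,experiment Identifier columns of the output table.
#' @param validate Run the schema validator on the generated table (default);
#'   the table is valid by construction, so bulk simulation loops may skip
#'   the re-check.
#' @return A validated trial tibble in the matching schema.
#' @examples
#' simulate_subject(subject_params(), "forced", n_trials = 13, seed = 42)
#' @export
simulate_subject <- function(params, design = c("forced", "free"), n_trials,
                             seed, subject = "synthetic",
                             species = "synthetic",
                             experiment = NULL, validate = TRUE) {
  stopifnot(inherits(params, "subject_params"))
  design <- match.arg(design)
  if (n_trials < 1) abort("n_trials must be at least 1.")
  experiment <- experiment %||% paste0("sim_", design)
  items <- params$items
  target <- target_item(items)
  w <- params$preference_weights
  withr::local_seed(seed)
  refused <- runif(n_trials) < params$refusal_prob
  if (design == "forced") {
    sel <- ifelse(refused, REFUSED,
                  items$item[sample.int(length(w), n_trials, replace = TRUE,
                                        prob = w)])
    u <- runif(n_trials)
    offered <- ifelse(refused, NONE,
               ifelse(sel == target,
                      ifelse(u < params$exchange_fidelity, target, NONE),
                      ifelse(u < params$spurious_offer_prob, sel, NONE)))
    out <- tibble(subject = subject, species = species,
                  experiment = experiment, trial = seq_len(n_trials),
                  selected = sel, arrived = as.integer(offered != NONE),
                  offered = offered, note = "")
    return(if (validate) validate_forced(out, items) else out)
  }
  k <- sample.int(length(params$k_distribution), n_trials, replace = TRUE,
                  prob = params$k_distribution)
  sets <- purrr::map(seq_len(n_trials), function(t) {
    if (refused[t]) character(0) else draw_without_replacement(items$item, w, k[t])
  })
  has_target <- purrr::map_lgl(sets, ~ target %in% .x)
  u <- runif(n_trials)
  offered <- vapply(seq_len(n_trials), function(t) {
    if (refused[t]) return(NONE)
    if (has_target[t]) {
      if (u[t] < params$exchange_fidelity) target else NONE
    } else if (u[t] < params$spurious_offer_prob) {
      sets[[t]][sample.int(k[t], 1)]
    } else {
      NONE
    }
  }, character(1))
  out <- tibble(subject = subject, species = species,
                experiment = experiment, trial = seq_len(n_trials),
                entered = as.integer(!refused),
                removed = vapply(sets, paste, "", collapse = ";"),
                first_touch = ifelse(refused, NONE,
                                     purrr::map_chr(sets, 1, .default = NONE)),
                offered = offered, note = "")
  if (validate) validate_free(out, items) else out
}

#' Rejection rate of a test under a synthetic subject
#'
#' Simulates `n_reps` independent subjects from `params`, scores each, runs
#' the named test with the exact method, and reports the proportion of
#' p-values at or below `alpha`. With a null subject (uniform weights) this
#' measures type-I error — which discreteness keeps at or below nominal —
#' and with a non-null subject it measures power.
#'
#' @inheritParams simulate_subject
#' @param test One of `"selection_forced"`, `"complete_sequence"`,
#'   `"selection_free"`, `"joint_behavior"`. The forced-design tests pair
#'   with `design = "forced"`; the free-selection tests with
#'   `design = "free"`.
#' @param alpha Nominal level.
#' @param n_reps Number of simulated subjects (>= 1).
#' @param chance Chance level for the binomial tests.
#' @return A one-row tibble: `test`, `design`, `alpha`, `n_reps`,
#'   `rejection_rate`, `mc_se` (binomial standard error
#'   `sqrt(r (1 - r) / n_reps)`).
#' @examples
#' estimate_rejection_rate(subject_params(), "forced", n_trials = 13,
#'                         test = "selection_forced", alpha = 0.05,
#'                         n_reps = 200, seed = 1)
#' @export
estimate_rejection_rate <- function(params, design = c("forced", "free"),
                                    n_trials,
                                    test = c("selection_forced",
                                             "complete_sequence",
                                             "selection_free",
                                             "joint_behavior"),
                                    alpha = 0.05, n_reps, seed,
                                    chance = 0.25) {
  design <- match.arg(design)
  test <- match.arg(test)
  if (n_reps < 1) abort("n_reps must be at least 1.")
  withr::local_seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  m <- n_items(params$items)
  pvals <- vapply(rep_seeds, function(s) {
    trials <- simulate_subject(params, design, n_trials, seed = s,
                               validate = FALSE)
    simulated_pvalue(trials, test, chance, m, params$items)
  }, numeric(1))
  r <- mean(pvals <= alpha)
  tibble(test = test, design = design, alpha = alpha, n_reps = n_reps,
         rejection_rate = r, mc_se = sqrt(r * (1 - r) / n_reps))
}

## Single-subject scoring + test on the hot simulation path. Base-R
## equivalent of score_forced/score_free + the exact tests (their agreement
## is pinned by a property test); the tibble/dplyr machinery is too costly
## at thousands of replicates.
simulated_pvalue <- function(trials, test, chance, m, items) {
  forced <- "selected" %in% names(trials)
  target <- target_item(items)
  if (test == "selection_forced") {
    if (!forced) abort("Test 'selection_forced' requires the forced design.")
    return(binom_upper_tail(sum(trials$selected == target),
                            nrow(trials), chance))
  }
  if (test == "complete_sequence") {
    n_seq <- if (forced) {
      sum(trials$selected == target & trials$offered == target)
    } else {
      sets <- split_removed(trials$removed)
      sum(vapply(sets, function(s) target %in% s, logical(1)) &
            trials$offered == target)
    }
    return(binom_upper_tail(n_seq, nrow(trials), chance))
  }
  if (forced) abort(sprintf("Test '%s' requires the free design.", test))
  sets <- split_removed(trials$removed)
  has_target <- vapply(sets, function(s) target %in% s, logical(1))
  entered <- trials$entered == 1L
  k <- lengths(sets)
  profiled <- entered & k >= 1L
  if (!any(profiled)) return(1)  # nothing selected: no evidence against null
  if (test == "selection_free") {
    pb_upper_tail(k[profiled] / m, sum(entered & has_target))
  } else {
    correct <- entered & (trials$offered == target |
                            (!has_target & trials$offered == NONE))
    binom_upper_tail(sum(correct), sum(profiled), 1 / m)
  }
}

#' Read subject parameters from a JSON or YAML file
#'
#' The file holds the [subject_params()] fields by name:
#' `preference_weights` (an object mapping item labels to weights),
#' `refusal_prob`, `k_distribution`, `exchange_fidelity`,
#' `spurious_offer_prob`. Missing fields take the constructor defaults.
#'
#' @param path File path ending in `.json`, `.yml` or `.yaml`.
#' @param items Item universe the weights are matched against.
#' @return A validated [subject_params()] object.
#' @examples
#' path <- system.file("extdata", "example_subject_params.json",
#'                     package = "apexchange")
#' read_subject_params(path)
#' @export
read_subject_params <- function(path, items = item_universe()) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML parameter files requires the 'yaml' package.")
    }
    yaml::read_yaml(path)
  } else {
    abort(sprintf("Unsupported parameter file extension '%s'.", ext))
  }
  w <- raw$preference_weights
  if (!is.null(w)) w <- unlist(w)
  subject_params(
    preference_weights = w,
    refusal_prob = raw$refusal_prob %||% 0,
    k_distribution = if (is.null(raw$k_distribution)) NULL
                     else unlist(raw$k_distribution),
    exchange_fidelity = raw$exchange_fidelity %||% 1,
    spurious_offer_prob = raw$spurious_offer_prob %||% 0,
    items = items)
}
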