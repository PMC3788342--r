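#' Score forced one-item selection trials
#'
#' Summarises a forced-selection trial table into per-subject,
#' per-experiment observed counts: the statistics that enter the exact
#' binomial tests. A trial is a correct selection when the target item was
#' touched or grabbed; refusals stay in the trial denominator (the design
#' offers the choice on every trial). A complete behavioural sequence is a
#' trial where the target was both selected and later offered at the deferred
#' exchange.
#'
#' An offered value of `UNKNOWN` in the forced design records an exchange
#' attempt whose object was not identified; it is determinately *not* the
#' target and scores as an incorrect exchange, as does any trial whose note
#' carries a `foreign:` annotation.
#'
#' @param trials A forced-design trial table (see [read_trials()]).
#' @param items Item universe; default the four-object set.
#'
#' @return A tibble with one row per subject x experiment and columns
#'   `n_trials`, `n_refusals`, `n_correct_selections`,
#'   `n_incorrect_selections`, `n_target_available`, `n_correct_exchanges`,
#'   `n_incorrect_exchanges`, `n_complete_sequences`.
#' @examples
#' score_forced(ape_exchange_trials("forced"))
#' @export
score_forced <- function(trials, items = item_universe()) {
  df <- validate_forced(trials, items)
  if (nrow(df) == 0) abort("Cannot score an empty trial table.")
  target <- target_item(items)
  dplyr::summarise(
    dplyr::group_by(df, .data$subject, .data$species, .data$experiment),
    n_trials = dplyr::n(),
    n_refusals = sum(.data$selected == REFUSED),
    n_correct_selections = sum(.data$selected == target),
    n_incorrect_selections = .data$n_trials - .data$n_correct_selections,
    n_target_available = .data$n_correct_selections,
    n_correct_exchanges = sum(.data$offered == target),
    n_incorrect_exchanges = sum(
      (.data$offered != NONE & .data$offered != target) |
        has_foreign_offer(.data$note)),
    n_complete_sequences = sum(.data$selected == target &
                                 .data$offered == target),
    .groups = "drop"
  )
}

#' Score free multi-item selection trials
#'
#' Summarises a free-selection (compartment) trial table into per-subject
#' observed counts. A correct selection is an entered trial in which the
#' target was among the items carried out; incorrect selections count
#' distractor *items* removed (a trial can contribute several). The joint
#' "correct behaviour" rule scores an entered trial as correct when the
#' target was offered at the exchange, or when nothing was offered on a trial
#' in which the target had not been selected — i.e. trading the right object,
#' or rightly declining to trade.
#'
#' When any entered trial has `offered = UNKNOWN` the per-trial exchange
#' record is incomplete and the offer-dependent counts (`n_correct_exchanges`,
#' `n_incorrect_exchanges`, `n_correct_behaviors`, `n_complete_sequences`)
#' are returned as `NA`; pass `aggregates` (see [ape_exchange_aggregates()])
#' to fill them from aggregate records.
#'
#' @param trials A free-design trial table.
#' @param items Item universe.
#' @param aggregates Optional tibble of aggregate exchange counts with
#'   columns `subject`, `experiment` and any of the offer-dependent count
#'   columns, used to patch rows the per-trial record leaves `NA`.
#'
#' @return A tibble with one row per subject x experiment and columns
#'   `n_trials`, `n_entered`, `n_correct_selections`,
#'   `n_incorrect_selections`, `n_target_available`, `n_correct_exchanges`,
#'   `n_incorrect_exchanges`, `n_correct_behaviors`, `n_complete_sequences`,
#'   `n_first_touch_target`.
#' @examples
#' score_free(ape_exchange_trials("free"), aggregates = ape_exchange_aggregates())
#' @export
score_free <- function(trials, items = item_universe(), aggregates = NULL) {
  df <- validate_free(trials, items)
  if (nrow(df) == 0) abort("Cannot score an empty trial table.")
  target <- target_item(items)
  sets <- split_removed(df$removed)
  df$has_target <- purrr::map_lgl(sets, ~ target %in% .x)
  df$n_removed <- lengths(sets)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$subject, .data$species, .data$experiment),
    n_trials = dplyr::n(),
    n_entered = sum(.data$entered == 1L),
    n_correct_selections = sum(.data$entered == 1L & .data$has_target),
    n_incorrect_selections = sum(.data$n_removed - .data$has_target),
    n_target_available = .data$n_correct_selections,
    unknown_offer = any(.data$entered == 1L & .data$offered == UNKNOWN),
    n_correct_exchanges = sum(.data$offered == target),
    n_incorrect_exchanges = sum(
      (.data$offered != NONE & .data$offered != target &
         .data$offered != UNKNOWN) | has_foreign_offer(.data$note)),
    n_correct_behaviors = sum(.data$entered == 1L &
      (.data$offered == target |
         (!.data$has_target & .data$offered == NONE &
            !has_foreign_offer(.data$note)))),
    n_complete_sequences = sum(.data$has_target & .data$offered == target),
    n_first_touch_target = sum(.data$first_touch == target),
    .groups = "drop"
  )
  na_cols <- c("n_correct_exchanges", "n_incorrect_exchanges",
               "n_correct_behaviors", "n_complete_sequences")
  out[out$unknown_offer, na_cols] <- NA_integer_
  out$unknown_offer <- NULL
  if (!is.null(aggregates)) {
    out <- patch_aggregates(out, aggregates, na_cols)
  }
  out
}

patch_aggregates <- function(scores, aggregates, cols) {
  agg <- as_tibble(aggregates)
  for (i in seq_len(nrow(agg))) {
    j <- which(scores$subject == agg$subject[i] &
                 scores$experiment == agg$experiment[i])
    for (col in intersect(cols, names(agg))) {
      scores[j, col] <- ifelse(is.na(scores[[col]][j]),
                               as.integer(agg[[col]][i]),
                               scores[[col]][j])
    }
  }
  scores
}

#' Per-trial removal counts for the free-selection null
#'
#' The free-selection chance model conditions on how many items the subject
#' actually carried out on each trial (its k-profile). `k_profile()` returns,
#' per subject, the removal count of every *entered* trial on which at least
#' one item was removed, in trial order; non-entered and empty-handed trials
#' carry no selection information and are excluded.
#'
#' @inheritParams score_free
#' @return A tibble with columns `subject`, `experiment`, `trial`, `k`.
#' @examples
#' k_profile(ape_exchange_trials("free"))
#' @export
k_profile <- function(trials, items = item_universe()) {
  df <- validate_free(trials, items)
  df$k <- lengths(split_removed(df$removed))
  df <- df[df$entered == 1L & df$k >= 1L, ]
  dplyr::arrange(df[c("subject", "experiment", "trial", "k")],
                 .data$subject, .data$experiment, .data$trial)
}

#' Tabulate spontaneous item preferences
#'
#' Counts, per subject, how often each item was selected in a forced-design
#' trial list, plus refusals; used to check that no subject spontaneously
#' preferred the exchangeable target before training.
#'
#' @inheritParams score_forced
#' @return A tibble with columns `subject`, `experiment`, `item` (item labels
#'   plus `REFUSED`) and `n`; within a subject x experiment the counts sum to
#'   the number of trials.
#' @examples
#' pref <- ape_exchange_trials("forced") |>
#'   dplyr::filter(experiment == "preference")
#' tabulate_preferences(pref)
#' @export
tabulate_preferences <- function(trials, items = item_universe()) {
  df <- validate_forced(trials, items)
  levels <- c(items$item, REFUSED)
  if (nrow(df) == 0) {
    return(tibble(subject = character(), experiment = character(),
                  item = character(), n = integer()))
  }
  counts <- dplyr::count(df, .data$subject, .data$experiment,
                         item = factor(.data$selected, levels = levels))
  counts <- tidyr::complete(counts,
                            tidyr::nesting(subject, experiment),
                            .data$item, fill = list(n = 0L))
  counts$item <- as.character(counts$item)
  dplyr::arrange(counts, .data$subject, .data$experiment)
}
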