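## Schema validation for trial tables. Every reader and fixture accessor
## funnels through these, so downstream scoring can assume the invariants.

forced_cols <- c("subject", "species", "experiment", "trial", "selected",
                 "arrived", "offered", "note")
free_cols <- c("subject", "species", "experiment", "trial", "entered",
               "removed", "first_touch", "offered", "note")

fail_row <- function(df, i, field, msg) {
  abort(sprintf("Invalid trial table: row %d (subject %s, trial %s), field '%s': %s",
                i, df$subject[i], df$trial[i], field, msg),
        class = "apexchange_validation_error")
}

check_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0("Trial table is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "apexchange_validation_error")
  }
}

check_trial_indices <- function(df) {
  by <- dplyr::group_by(df, .data$subject, .data$experiment)
  bad <- dplyr::filter(dplyr::summarise(
    by, ok = identical(sort(.data$trial), seq_len(dplyr::n())),
    .groups = "drop"), !.data$ok)
  if (nrow(bad)) {
    abort(sprintf(
      "Trial indices for subject %s, experiment %s are not a contiguous 1..n sequence.",
      bad$subject[1], bad$experiment[1]),
      class = "apexchange_validation_error")
  }
}

has_foreign_offer <- function(note) {
  grepl("foreign:", note %||% "", fixed = TRUE)
}

#' @rdname read_trials
#' @export
validate_forced <- function(trials, items = item_universe()) {
  df <- as_tibble(trials)
  check_columns(df, forced_cols)
  if (nrow(df) == 0) return(df[forced_cols])
  df$trial <- as.integer(df$trial)
  df$arrived <- as.integer(df$arrived)
  df$note <- ifelse(is.na(df$note), "", as.character(df$note))
  target <- target_item(items)
  sel_ok <- c(items$item, REFUSED, UNKNOWN)
  off_ok <- c(items$item, NONE, UNKNOWN)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$selected[i]) || !df$selected[i] %in% sel_ok)
      fail_row(df, i, "selected",
               sprintf("'%s' is not an item label, REFUSED or UNKNOWN.",
                       df$selected[i]))
    if (is.na(df$offered[i]) || !df$offered[i] %in% off_ok)
      fail_row(df, i, "offered",
               sprintf("'%s' is not an item label, NONE or UNKNOWN.",
                       df$offered[i]))
    if (!df$arrived[i] %in% c(0L, 1L))
      fail_row(df, i, "arrived", "must be 0 or 1.")
    if (df$selected[i] == REFUSED && identical(df$offered[i], target))
      fail_row(df, i, "offered",
               "the target cannot be offered on a refused trial (nothing was carried).")
  }
  check_trial_indices(df)
  df[forced_cols]
}

split_removed <- function(removed) {
  strsplit(ifelse(is.na(removed) | removed == "", "", removed), ";",
           fixed = TRUE)
}

#' @rdname read_trials
#' @export
validate_free <- function(trials, items = item_universe()) {
  df <- as_tibble(trials)
  check_columns(df, free_cols)
  if (nrow(df) == 0) return(df[free_cols])
  df$trial <- as.integer(df$trial)
  df$entered <- as.integer(df$entered)
  df$note <- ifelse(is.na(df$note), "", as.character(df$note))
  df$removed <- ifelse(is.na(df$removed), "", as.character(df$removed))
  target <- target_item(items)
  touch_ok <- c(items$item, NONE, UNKNOWN)
  removed_sets <- split_removed(df$removed)
  for (i in seq_len(nrow(df))) {
    set <- removed_sets[[i]]
    if (!df$entered[i] %in% c(0L, 1L))
      fail_row(df, i, "entered", "must be 0 or 1.")
    if (length(bad <- setdiff(set, items$item)))
      fail_row(df, i, "removed",
               sprintf("unknown item label '%s'.", bad[1]))
    if (anyDuplicated(set))
      fail_row(df, i, "removed", "duplicate item labels.")
    if (is.na(df$first_touch[i]) || !df$first_touch[i] %in% touch_ok)
      fail_row(df, i, "first_touch",
               sprintf("'%s' is not an item label, NONE or UNKNOWN.",
                       df$first_touch[i]))
    if (is.na(df$offered[i]) || !df$offered[i] %in% touch_ok)
      fail_row(df, i, "offered",
               sprintf("'%s' is not an item label, NONE or UNKNOWN.",
                       df$offered[i]))
    if (df$entered[i] == 0L) {
      if (length(set))
        fail_row(df, i, "removed", "items removed on a non-entered trial.")
      if (df$first_touch[i] != NONE)
        fail_row(df, i, "first_touch", "must be NONE on a non-entered trial.")
    }
    if (identical(df$offered[i], target) && !target %in% set)
      fail_row(df, i, "offered",
               "the target cannot be offered unless it was removed.")
    if (df$offered[i] %in% items$item && !df$offered[i] %in% set &&
        !has_foreign_offer(df$note[i]))
      fail_row(df, i, "offered",
               "an offered item must be in the removed set unless a 'foreign:' note explains it.")
  }
  check_trial_indices(df)
  df[free_cols]
}
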