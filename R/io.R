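#' Read and write trial tables
#'
#' Trial tables are flat, one row per trial, in one of two schemas.
#'
#' **Forced design** (tray; one item per trial): `subject`, `species`,
#' `experiment`, `trial` (1-based, contiguous per subject and experiment),
#' `selected` (an item label, `REFUSED` or `UNKNOWN`), `arrived` (0/1, whether
#' the subject showed up at the exchange location), `offered` (item label,
#' `NONE` or `UNKNOWN`), `note` (free text; a note containing `foreign:` marks
#' an attempted exchange with a non-tray object and scores as an incorrect
#' exchange).
#'
#' **Free design** (compartment; any subset per trial): `subject`, `species`,
#' `experiment`, `trial`, `entered` (0/1), `removed` (semicolon-joined item
#' labels, possibly empty), `first_touch` (item label, `NONE` or `UNKNOWN`),
#' `offered` (item label, `NONE` or `UNKNOWN`), `note`.
#'
#' CSV files are UTF-8 with a header row. JSON files nest the same fields as
#' subject records: an object with `design` and `subjects`, each subject
#' holding `name`, `species` and an `experiments` map from experiment id to an
#' ordered trial array. Both formats round-trip losslessly: CSV preserves row
#' order exactly, JSON returns rows grouped by subject (identical tables after
#' arranging by subject, experiment and trial).
#'
#' @param path File path. Format is taken from the extension (`.csv`/`.json`)
#'   unless `format` is given.
#' @param format `"csv"` or `"json"` (default `"auto"`).
#' @param design `"forced"`, `"free"`, or `"auto"` to detect from the columns
#'   (presence of `entered`).
#' @param items Item universe the labels are validated against.
#' @param trials A trial table in one of the two schemas.
#'
#' @return `read_trials()` returns a validated tibble; `write_trials()`
#'   returns `path` invisibly. `validate_forced()` / `validate_free()` return
#'   the validated tibble or raise a validation error naming the offending row
#'   and field.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_trials(ape_exchange_trials("free"), path)
#' identical(read_trials(path), ape_exchange_trials("free"))
#' @export
read_trials <- function(path, format = c("auto", "csv", "json"),
                        design = c("auto", "forced", "free"),
                        items = item_universe()) {
  format <- resolve_format(path, match.arg(format))
  design <- match.arg(design)
  df <- if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character(),
                                                  trial = readr::col_integer()),
                    progress = FALSE)
  } else {
    json_to_trials(jsonlite::read_json(path))
  }
  if (nrow(df) == 0 && design == "auto") {
    design <- if ("entered" %in% names(df)) "free" else "forced"
  }
  if (design == "auto") {
    design <- if ("entered" %in% names(df)) "free" else "forced"
  }
  if (design == "forced") validate_forced(df, items) else validate_free(df, items)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path, format = c("auto", "csv", "json")) {
  format <- resolve_format(path, match.arg(format))
  design <- if ("entered" %in% names(trials)) "free" else "forced"
  trials <- if (design == "free") validate_free(trials) else validate_forced(trials)
  if (format == "csv") {
    readr::write_csv(trials, path, progress = FALSE)
  } else {
    jsonlite::write_json(trials_to_json(trials, design), path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

resolve_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) return(ext)
  abort(sprintf("Cannot infer format from extension '%s'; pass format=.", ext))
}

trials_to_json <- function(trials, design) {
  ## subjects and experiments keep first-appearance order so a write/read
  ## cycle reproduces the table exactly
  trial_cols <- setdiff(names(trials), c("subject", "species", "experiment"))
  list(
    design = design,
    subjects = purrr::map(unique(trials$subject), function(nm) {
      df <- trials[trials$subject == nm, ]
      exps <- setNames(
        purrr::map(unique(df$experiment), function(ex) {
          e <- df[df$experiment == ex, trial_cols]
          purrr::transpose(as.list(e[order(e$trial), ]))
        }),
        unique(df$experiment))
      list(name = nm, species = df$species[1], experiments = exps)
    })
  )
}

json_to_trials <- function(x) {
  if (is.null(x$subjects) || length(x$subjects) == 0) {
    return(tibble(subject = character(), species = character(),
                  experiment = character(), trial = integer()))
  }
  purrr::map_dfr(x$subjects, function(s) {
    purrr::imap_dfr(s$experiments, function(rows, exp) {
      df <- purrr::map_dfr(rows, ~ as_tibble(purrr::map(.x, ~ .x %||% "")))
      df$experiment <- exp
      df$subject <- s$name
      df$species <- s$species
      df
    })
  })
}
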