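test_that("item universe enforces a unique target and minimum size", {
  items <- item_universe()
  expect_equal(nrow(items), 4)
  expect_equal(target_item(items), "metal")
  expect_equal(sum(items$is_target), 1)
  expect_error(item_universe(c("a")), "at least 2")
  expect_error(item_universe(c("a", "a", "b")), "unique")
  expect_error(item_universe(c("a", "NONE"), target = "a"), "reserved")
  expect_error(item_universe(c("a", "b"), target = "c"), "not among")
})

test_that("bundled fixtures cover four subjects with contiguous trials", {
  forced <- ape_exchange_trials("forced")
  free <- ape_exchange_trials("free")
  expect_setequal(unique(c(forced$subject, free$subject)),
                  c("Manda", "Maria-Magdalena", "Naong", "Dunja"))
  expect_setequal(unique(forced$experiment), c("preference", "exp1"))
  expect_equal(unique(free$experiment), "exp2")
  # every subject-experiment block is 1..n
  for (df in list(forced, free)) {
    blocks <- split(df$trial, paste(df$subject, df$experiment))
    for (b in blocks) expect_equal(sort(b), seq_along(b))
  }
  # free trials: 12 per subject
  expect_equal(unname(table(free$subject)), rep(12L, 4), ignore_attr = TRUE)
})

test_that("forced scoring reproduces the recorded tray-experiment counts", {
  scores <- score_forced(ape_exchange_trials("forced"))
  exp1 <- scores[scores$experiment == "exp1", ]
  get <- function(s) exp1[exp1$subject == s, ]

  naong <- get("Naong")
  expect_equal(naong$n_trials, 13L)
  expect_equal(naong$n_correct_selections, 12L)
  expect_equal(naong$n_correct_exchanges, 11L)
  expect_equal(naong$n_complete_sequences, 11L)
  expect_equal(naong$n_incorrect_exchanges, 1L)

  manda <- get("Manda")
  expect_equal(manda$n_correct_selections, 9L)
  expect_equal(manda$n_correct_exchanges, 9L)
  expect_equal(manda$n_complete_sequences, 9L)
  expect_equal(manda$n_incorrect_exchanges, 0L)

  dunja <- get("Dunja")
  expect_equal(dunja$n_trials, 14L)
  expect_equal(dunja$n_correct_selections, 11L)
  expect_equal(dunja$n_correct_exchanges, 0L)
  expect_equal(dunja$n_incorrect_exchanges, 4L)  # foreign-object attempts
})

test_that("an all-refusal forced list scores zero everywhere but n_trials", {
  df <- tibble::tibble(subject = "s", species = "x", experiment = "e",
                       trial = 1:5, selected = "REFUSED", arrived = 0L,
                       offered = "NONE", note = "")
  sc <- score_forced(df)
  expect_equal(sc$n_trials, 5L)
  expect_equal(sc$n_refusals, 5L)
  expect_equal(sc$n_correct_selections, 0L)
  expect_equal(sc$n_correct_exchanges, 0L)
  expect_equal(sc$n_complete_sequences, 0L)
})

test_that("free scoring reproduces the recorded compartment-experiment counts", {
  scores <- score_free(ape_exchange_trials("free"),
                       aggregates = ape_exchange_aggregates())
  get <- function(s) scores[scores$subject == s, ]

  mm <- get("Maria-Magdalena")
  expect_equal(mm$n_correct_selections, 7L)
  expect_equal(mm$n_correct_exchanges, 7L)
  expect_equal(mm$n_correct_behaviors, 12L)
  expect_equal(mm$n_complete_sequences, 7L)
  expect_equal(mm$n_first_touch_target, 6L)

  manda <- get("Manda")
  expect_equal(manda$n_correct_selections, 12L)
  expect_equal(manda$n_first_touch_target, 11L)
  expect_equal(manda$n_correct_exchanges, 6L)   # from the aggregate record
  expect_equal(manda$n_correct_behaviors, 6L)

  naong <- get("Naong")
  expect_equal(naong$n_entered, 8L)
  expect_equal(naong$n_correct_selections, 7L)
  expect_equal(naong$n_correct_behaviors, 7L)
  expect_equal(naong$n_incorrect_exchanges, 1L)

  dunja <- get("Dunja")
  expect_equal(dunja$n_entered, 0L)
  expect_equal(dunja$n_incorrect_exchanges, 2L)  # faeces and sponge offers
})

test_that("offer-dependent counts are NA without the aggregate record", {
  scores <- score_free(ape_exchange_trials("free"))
  manda <- scores[scores$subject == "Manda", ]
  expect_true(is.na(manda$n_correct_exchanges))
  expect_true(is.na(manda$n_correct_behaviors))
  # other subjects have complete per-trial offers
  expect_false(anyNA(scores[scores$subject != "Manda", ]))
})

test_that("k-profiles match the reconstructed per-trial removal counts", {
  prof <- fixture_k_profiles()
  expect_equal(prof[["Maria-Magdalena"]], c(4, 2, 1, 1, 1, 1, 1, 2, 1, 2, 1, 1))
  expect_equal(prof[["Manda"]], c(3, 3, 2, 2, 1, 1, 2, 1, 1, 2, 1, 1))
  expect_equal(prof[["Naong"]], c(1, 1, 1, 1, 1, 1, 2, 1))
  expect_null(prof[["Dunja"]])  # never entered: no profiled trials
  # profile sums equal total items removed across entered trials
  expect_equal(sum(prof[["Maria-Magdalena"]]), 7 + 5 + 4 + 2)
  expect_equal(sum(prof[["Manda"]]), 12 + 8)
})

test_that("k_profile of a table with no entered trials is empty", {
  df <- tibble::tibble(subject = "s", species = "x", experiment = "e",
                       trial = 1:3, entered = 0L, removed = "",
                       first_touch = "NONE", offered = "NONE", note = "")
  expect_equal(nrow(k_profile(df)), 0)
})

test_that("preference tabulation matches the recorded counts and sums to n", {
  pref <- dplyr::filter(ape_exchange_trials("forced"),
                        experiment == "preference")
  tab <- tabulate_preferences(pref)
  get <- function(s, it) tab$n[tab$subject == s & tab$item == it]
  expect_equal(get("Manda", "wood"), 12L)
  expect_equal(get("Manda", "rope"), 2L)
  expect_equal(get("Manda", "jute"), 1L)
  expect_equal(get("Manda", "metal"), 0L)
  expect_equal(get("Manda", "REFUSED"), 0L)
  expect_equal(get("Naong", "rope"), 3L)
  expect_equal(get("Naong", "wood"), 4L)
  expect_equal(get("Naong", "metal"), 3L)
  expect_equal(get("Naong", "REFUSED"), 4L)
  sums <- tapply(tab$n, tab$subject, sum)
  expect_true(all(sums == 15))
  # no subject spontaneously preferred the metal strip
  metal <- tab$n[tab$item == "metal"]
  expect_true(all(metal <= 3))
})

test_that("trial tables round-trip through CSV and JSON", {
  free <- ape_exchange_trials("free")
  forced <- ape_exchange_trials("forced")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")

  write_trials(free, csv)
  expect_identical(read_trials(csv), free)
  write_trials(free, js)
  expect_identical(read_trials(js), free)

  write_trials(forced, csv)
  expect_identical(read_trials(csv), forced)
  # JSON nests by subject, so equality holds after canonical ordering
  write_trials(forced, js)
  canon <- function(df) dplyr::arrange(df, subject, experiment, trial)
  expect_identical(canon(read_trials(js)), canon(forced))
})

test_that("the installed extdata files equal the in-code fixtures", {
  for (design in c("forced", "free")) {
    path <- system.file("extdata", paste0(design, "_trials.csv"),
                        package = "apexchange")
    expect_identical(read_trials(path), ape_exchange_trials(design))
  }
})

test_that("validation errors name the offending row and field", {
  good <- ape_exchange_trials("forced")
  bad <- good
  bad$selected[3] <- "banana"
  expect_error(validate_forced(bad), "row 3.*selected.*banana")

  dup <- good
  dup$trial[2] <- 1L
  expect_error(validate_forced(dup), "contiguous")

  refuse <- good[good$subject == "Manda" & good$experiment == "exp1", ]
  refuse$selected[1] <- "REFUSED"
  refuse$offered[1] <- "metal"
  expect_error(validate_forced(refuse), "refused trial")

  free <- ape_exchange_trials("free")
  ghost <- free
  ghost$removed[ghost$entered == 0][1] <- "metal"
  expect_error(validate_free(ghost), "non-entered")

  phantom <- free[free$subject == "Naong", ]
  phantom$offered[4] <- "metal"  # trial 4: not entered, nothing removed
  expect_error(validate_free(phantom), "unless it was removed")
})

test_that("an empty trial table loads as an empty validated table", {
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ape_exchange_trials("forced")[0, ], csv)
  out <- read_trials(csv, design = "forced")
  expect_equal(nrow(out), 0)
  expect_error(score_forced(out), "empty")
})
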