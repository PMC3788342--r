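Package: apexchange
Title: Scoring and Chance Models for Deferred-Exchange Experiments in Great Apes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing deferred token-exchange experiments in
    comparative cognition, where a subject selects one or more objects and may
    later trade a trained target object with a human for a food reward. Provides
    validated trial-table input/output, scoring rules for forced one-item and
    free multi-item selection designs, exact one-tailed binomial tests at a
    configurable chance level (default 25 percent for four equally available
    items), an exact Poisson-binomial tail and seeded Monte Carlo construction
    of the free-selection null (conditioning on the observed per-trial removal
    counts), a joint selection-and-exchange null for "correct behaviour"
    scoring, a generative model of synthetic subjects for power and type-I
    error studies, and a one-command replication pipeline over the bundled
    four-subject dataset (two chimpanzees, two orangutans).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
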