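# apexchange

Statistical analysis of deferred token-exchange experiments in great apes.

In these experiments an ape chooses among four objects — one of which (a
metal strip) has been trained to be tradeable with a human for food — and the
exchange opportunity only arrives after a delay and at a different location.
The question is whether the animal selects, transports and later trades the
currently useless object, i.e. whether it prepares for a future situation
outside its present sensory scope. The package is for comparative-cognition
researchers who want the scoring rules and the (slightly unusual) chance
models for this paradigm as tested, reusable code: validated trial tables,
exact tests, conditioned Monte Carlo nulls, a synthetic-subject simulator for
power and type-I error studies, and a one-call replication of the bundled
four-subject dataset (two chimpanzees, two orangutans).

## The statistics at the core

**Forced one-item selection.** One tray, four items, one choice per trial:
the number of correct selections under chance is
X ~ Binomial(n, 1/4), and every test is the exact one-tailed upper tail
P(X ≥ x) (`binom_upper_tail()`, direct summation). The same conservative
1/4 tail is applied to *complete behavioural sequences* (select the target,
transport it, exchange it).

**Free multi-item selection.** When the subject may carry out any subset of
the m = 4 items, a fixed-p binomial no longer applies. The chance model
conditions on the observed per-trial removal counts k₁,…,kₙ (the
*k-profile*): under the null each trial's removal set is a uniform draw
without replacement, so the target is included with probability kₜ/m
independently across trials, and the retrieval count is
**Poisson-binomial** with those probabilities. `free_selection_test()`
computes the exact tail by convolution (`pb_upper_tail()`) or by a seeded
50,000-replicate Monte Carlo replay.

**Joint selection-and-exchange.** A *correct behaviour* is exchanging the
target, or refusing to trade when the target was not selected. The null
agent removes kₜ random items and offers one of them uniformly at random;
since (kₜ/m)·(1/kₜ) = 1/m, its correct-behaviour count is exactly
Binomial(n, 1/m) (`joint_behavior_test()`).

## Worked example

The second chimpanzee (Maria-Magdalena) carried the target out of the
compartment on 7 of 12 trials, but also took distractors — four items on
trial 1, two on trials 2, 8 and 10:

```r
library(apexchange)
library(dplyr)

trials  <- ape_exchange_trials("free")
profile <- k_profile(trials) |> filter(subject == "Maria-Magdalena")
null    <- free_selection_null(profile$k)
null
#> Free-selection null: 12 trials, 4 items
#>   k-profile: 4 2 1 1 1 1 1 2 1 2 1 1

free_selection_test(null, observed = 7)
#> Exchange test: target_retrievals
#>   observed 7 of 12;  null: uniform draw of k_t of 4 items per trial (Poisson-binomial)
#>   one-tailed p = 0.094  (exact)
```

Her selection alone is *not* above chance (p = 0.094): taking several items
buys inclusion by luck. But she exchanged the target all 7 times she had it
and offered nothing in the other 5 trials — 12 of 12 correct behaviours
under the joint rule:

```r
joint_behavior_test(null, observed_correct = 12)
#> Exchange test: correct_behaviors
#>   observed 12 of 12;  null: random removal then always offer (per-trial correct prob 0.25)
#>   one-tailed p = <0.001  (exact)

score_free(trials, aggregates = ape_exchange_aggregates()) |>
  complete_sequence_test() |>
  filter(subject == "Maria-Magdalena") |>
  select(statistic, observed, n, p_value)
#> # A tibble: 1 × 4
#>   statistic          observed     n p_value
#>   <chr>                 <int> <int>   <dbl>
#> 1 complete_sequences        7    12  0.0143
```

So the dissociation the paradigm is designed to expose shows up directly:
chance-level selection counts, far-above-chance *use* of what was selected.
`run_replication()` runs every subject and test in one call and returns a
report with `tidy()`/`glance()` methods, `autoplot()` figures and
`render_report()` output in markdown, TSV or JSON; two recorded p-values
that cannot be derived from the stated scoring rules are flagged
`NOT_REPRODUCED` rather than matched (see the methods vignette).

A thin command-line wrapper ships in `inst/cli/apexchange.R` with
`replicate`, `analyze`, `simulate` and `power` subcommands.

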