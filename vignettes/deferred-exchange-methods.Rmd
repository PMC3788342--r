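---
title: "Scoring rules and chance models for deferred-exchange experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring rules and chance models for deferred-exchange experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apexchange)
library(dplyr)
```

## The experimental paradigm

In a deferred token-exchange experiment an ape is given access to a set of
objects, exactly one of which — here a metal strip — has been trained to be
tradeable with a human for a food reward. The catch is temporal and spatial
displacement: the exchange opportunity arrives only after a delay (15 min in
the bundled dataset) and at a different location, with no human present at
the moment of choice. Succeeding therefore requires selecting the currently
useless object, carrying it, and producing it when the future exchange
situation materialises.

Two designs probe this ability:

* **Forced one-item selection** — four items on a tray, the subject may take
  exactly one (or refuse). One trial, one choice, chance level 1/4.
* **Free multi-item selection** — the four items lie in a compartment the
  subject may enter alone; *any subset* may be carried out. A fixed chance
  level no longer exists, because taking more items raises the probability
  of holding the target by luck.

The package implements validated trial tables for both designs, the scoring
rules that reduce them to count statistics, the exact tests and conditioned
chance models those counts are evaluated against, a generative model of
synthetic subjects, and a one-call replication pipeline
(`run_replication()`) over the bundled four-subject dataset (two
chimpanzees, two orangutans).

## Scoring rules

`score_forced()` counts, per subject and experiment: correct selections
(target touched or grabbed), correct exchanges (target offered at the
deferred exchange), and *complete behavioural sequences* — trials in which
the target was selected **and** exchanged. Refusal trials remain in the
denominator: the opportunity was offered, so a refusal is a failure of the
sequence, which is the conservative reading used throughout.

`score_free()` adds the free-design quantities: entered trials, trials on
which the target was among the removed items, first touches of the target,
and *correct behaviours* under the joint rule — exchanging the target, or
offering nothing on a trial where the target had not been selected. Both
halves of the rule express the same competence: trade exactly when you hold
the means to.

`k_profile()` extracts the conditioning variable of the free-design chance
model: the number of items removed on each entered trial with at least one
removal, in trial order.

## The chance models

**Forced design.** With four equally available items, the number of correct
selections under chance is $X \sim \mathrm{Binomial}(n, 1/4)$, and all tests
are exact one-tailed upper tails $P(X \ge x)$ computed by direct summation
of the mass function (`binom_upper_tail()`). The same tail, at the same
conservative 1/4, is applied to complete behavioural sequences.

**Free design, selection stage.** The model *conditions on the observed
removal counts* $k_1, \dots, k_n$: under the null, the $k_t$ items carried
out on trial $t$ are a uniform draw without replacement from the $m = 4$
available, so the target is included with probability $k_t/m$,
independently across trials. The number of target retrievals is then
Poisson-binomial with those inclusion probabilities. `pb_upper_tail()`
evaluates the exact tail by iterative convolution (dynamic programming over
counts, $O(n^2)$, exact to floating-point rounding), and
`free_selection_test()` offers both this exact evaluation and a seeded
Monte Carlo replay (default 50,000 replicates) that estimates the tail as a
plain proportion of replicates at or above the observed count. An add-one
estimator $(b+1)/(n+1)$ is available by flag but non-default: the plain
proportion is the estimator that reproduces the recorded three-decimal
value 0.094 for the second chimpanzee.

**Free design, joint stage.** To test selection *and* exchange jointly, the
null agent is extended with an exchange policy. The default, and the choice
we consider the natural "pure chance" agent, always offers exactly one of
its $k_t$ drawn items, uniformly at random. Because the draw itself is
uniform, the offer is the target with probability
$(k_t/m)\cdot(1/k_t) = 1/m$ exactly, so the correct-behaviour count under
the null is $\mathrm{Binomial}(n, 1/m)$ regardless of the profile — a
pleasingly clean reduction that the exact branch uses directly, while the
Monte Carlo branch still replays the two-stage agent. An alternative
`offer_or_refuse` policy, under which the agent picks uniformly among its
$k_t$ items *or* refusing ($k_t + 1$ options, per-trial correct probability
$1/(k_t+1)$), is provided for sensitivity analysis but is not the default:
a refusing chance agent credits the null with the competence under test
(declining when empty-handed), which we judged too generous.

## Data notes: reconstructions and irreproducible values

The bundled per-trial tables are reconstructed from an itemised narrative
record, which determines them uniquely up to four caveats, all encoded as
`UNKNOWN` tokens or aggregate rows rather than invented data:

* One chimpanzee's (Manda's) six successful compartment-trial exchanges are
  identified only in aggregate; her per-trial `offered` entries are
  `UNKNOWN` and the counts come from `ape_exchange_aggregates()`.
  `score_free()` returns `NA` for offer-dependent counts whenever an
  entered trial has an `UNKNOWN` offer, so the incompleteness is explicit.
* The identities of a few incorrectly selected or offered objects in the
  tray experiment are unrecorded; `UNKNOWN` there means "determinately not
  the target" and scores as an incorrect selection/exchange.
* The narrative says Manda carried the target *alone* in five compartment
  trials, but the itemised distractor lists (rope on trials 2, 3, 4, 10;
  wood on 1, 2, 7; jute on 1) force six singleton trials. The tables follow
  the itemised lists, which are the finer-grained record.
* The overview table's "incorrect selections" column counts distractor
  items for the chimpanzees but appears to count trials for the male
  orangutan (1 where his two-item trial implies 2). `render_report()` uses
  the item-count convention consistently.

Two recorded p-values cannot be reproduced from the stated rules at any
simulation scale, and `run_replication()` flags them `NOT_REPRODUCED`
instead of matching them:

1. Manda's compartment complete-sequence test is recorded as $p = 0.11$ for
   6 of 12; the one-tailed tail at chance 1/4 is 0.054, and a symmetric
   two-sided construction gives 0.086. No stated construction yields 0.11.
2. Manda's joint correct-behaviour test is recorded as $p < 0.001$,
   although under the stated rule her six refusals-while-holding-the-target
   score as incorrect, giving 6/12 and again 0.054. Her record is the one
   case where selection was perfect but exchange was intermittent, so the
   joint rule's refusal clause never helps her; we report the honest 0.054.

## Synthetic subjects

`subject_params()` describes a generative subject: preference weights over
items (selection proportional to weight; free-design removals by successive
weighted draws without replacement), a refusal probability, a distribution
over removal counts, and an exchange policy (`exchange_fidelity`,
`spurious_offer_prob`). `simulate_subject()` emits schema-valid trial
tables, deterministically given a seed.

The generator emulates what the chance models need — marginal selection
frequencies, removal-count laws, refusals, imperfect exchange — and
deliberately omits what they do not: learning or drift across trials,
order effects within a trial, and social modulation of exchange. Passing
tests on synthetic data therefore demonstrate the statistical machinery,
not ecological realism.

The null ("chance") subjects used for type-I error checks are: uniform
weights for the selection tests (with any removal-count law — the
free-selection test conditions on the realised profile, so its level is
controlled regardless); uniform weights with full fidelity for the
complete-sequence test (select the target by luck with probability 1/4,
then always exchange it — exactly the conservative 1/4 convention); and
uniform weights with `spurious_offer_prob = 1` and single-item removals for
the joint test (always offer whatever was taken, correct with probability
1/4). `estimate_rejection_rate()` with 2,000 replicates confirms rejection
at or below nominal for all four tests; exact tests on discrete counts are
conservative, so rates sit visibly below $\alpha$.

For power, the dissociation seen in the data is easily reproduced: a
subject with an inclusion pattern like the second chimpanzee's profile and
perfect exchange fidelity is detected by the joint test at $\alpha = 0.001$
while the selection-only test cannot reject at $\alpha = 0.05$ — her
selection evidence is diluted by multi-item trials, her exchange behaviour
is not.

## Numerical and design choices

* Exact binomial tails are direct summations of `dbinom()` terms —
  absolute error far below $10^{-12}$ at these trial counts; the
  Poisson-binomial convolution is validated against $2^n$ enumeration up
  to $n = 12$ in the test suite.
* Monte Carlo agreement with exact tails is asserted via the central
  99.7% binomial band on the replicate hit count, which equals the
  familiar $\pm 3$ standard errors for moderate tails and handles the very
  small ones ($10^{-5}$ and below, where the hit count is essentially
  Poisson) without false alarms.
* Every stochastic entry point takes an explicit integer seed and uses a
  local RNG stream (`withr::local_seed()`), so library calls never disturb
  the caller's generator state; `run_replication()` records its seed in
  the report.
* Simulation sizes are chosen to keep the whole suite fast while leaving
  no statistical ambiguity: 50,000 replicates for Monte Carlo
  cross-checks (matching the recorded analysis), 2,000 subjects per
  type-I sweep, 8,000–10,000 trials for law-of-large-numbers checks.
* `estimate_rejection_rate()` scores its simulated subjects through a
  base-R fast path whose agreement with `score_forced()`/`score_free()`
  and the public tests is pinned by a property test; the tibble pipeline
  is the user-facing surface, not the inner loop.
* P-values print at three decimals with `<0.001` below that
  (`format_p()`), matching the reporting granularity of the original
  analyses.

## Limitations

The free-design null treats trials as independent and removal counts as
fixed by conditioning; it cannot detect strategies that manipulate *how
many* items to take. The joint null's offer policy is a modelling choice
(see above), and the package intentionally ships the alternative rather
than claiming uniqueness. With four subjects and at most 14 trials each,
every conclusion is per-individual; nothing here pools across subjects, and
the package provides no population-level inference.
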