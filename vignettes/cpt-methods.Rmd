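---
title: "Modeling risky choice on the MDM task: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling risky choice on the MDM task: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmcpt)
```

## The model and its assumptions

`mdmcpt` implements the cumulative prospect theory (CPT) account of binary
risky choice on a two-gamble task. A gamble pays `x` points with probability
`p` and `y` with `1 - p`. Choices are assumed to arise from four
subject-level parameters:

| parameter | role | unit | default (simulator) |
|---|---|---|---|
| `alpha` | curvature of the power value function (value discrimination); shared across gain and loss domains | dimensionless, > 0 | 0.85 (0.55 in the OCD group) |
| `lam`   | loss aversion: multiplier on the disutility of losses | dimensionless, > 0 | 1.3 |
| `gamma` | curvature of the probability weighting function (inverse-S when < 1) | dimensionless, > 0 | 0.7 |
| `delta` | elevation of the weighting function | dimensionless, > 0 | 0.9 |

The value function is `v(x) = x^alpha` for gains and `-lam * (-x)^alpha`
for losses; the weighting function is
`w(p) = delta p^gamma / (delta p^gamma + (1-p)^gamma)`. Single-domain
gambles are valued with complementary weights,
`f = w(p) v(x) + (1 - w(p)) v(y)`; mixed gambles weight the gain and the
loss separately, `f = w(p) v(x) + w(1-p) v(y)`. Choice is logistic in the
utility difference with sensitivity `k` fixed at 1, so that nothing outside
the theory is estimated; `fit_settings(k = )` exists for sensitivity
analysis only.

Two modeling consequences are worth stating explicitly:

- At identity parameters the model is an expected-value maximizer with
  logistic noise on the raw point scale; utilities reach `±200`, so the
  `k = 1` logistic saturates on most trials. Choice probabilities are
  therefore clipped to `[1e-12, 1 - 1e-12]` before entering any
  log-likelihood, which keeps the objective finite everywhere in the
  parameter box.
- On loss-only trials `lam` multiplies both utilities, so it cancels from
  the *sign* of the utility difference: the modal choice is
  `lam`-invariant. Under the stochastic choice rule, however, `lam`
  rescales the utility *difference* and hence the choice noise on those
  trials. The package implements the equations as written and does not
  try to resolve this tension; the test suite asserts the sign-invariance
  property, which is what holds mathematically.

The likelihood treats choices as conditionally independent across trials
given the parameters; there is no learning, sequence, or response-time
component, by design.

## The task generator

The published structure of the 126-trial MDM task is reproduced exactly:
42 trials per type (gain-only, loss-only, mixed-outcome), values on a grid
of multiples of 5 in `[-200, 200]`, probabilities in
`{.05, .30, .50, .70, .95}`, 17 trials in which both gambles carry the same
probability, 14 of them single-domain. The concrete gamble pairs of the
original instrument were never published, so `generate_task()` synthesizes
one admissible instantiation per seed; every structural constraint is
checked by `validate_task()` and all counts are configurable through
`task_config()`.

Where the published record is silent, the generator makes these choices:

- **Outcome convention.** Within a gamble, `x` (carried with probability
  `p`) is the more extreme outcome in single-domain gambles and the gain in
  mixed gambles. Mixed-gamble magnitudes are otherwise free: constraining
  `|x| >= |y|` in mixed gambles would exclude loss-dominant stimuli, which
  are exactly the trials that identify `lam`.
- **EV-gap band.** Every trial's two gambles must differ in expected value
  by an amount in `[2.5, 40]` points (`ev_gap_min` / `ev_gap_max`). The
  lower bound makes the EV-optimal choice well defined on every trial,
  which the optimality analysis needs. The upper bound is a stimulus-design
  choice: a task in which one gamble trivially dominates on every trial
  produces near-deterministic choices under the `k = 1` logistic, and such
  data carry almost no information about the value and weighting functions
  — in our simulations the likelihood develops a ridge and maximum
  likelihood estimates drift far from the generating values. Keeping a
  substantial share of trials near indifference is what makes the stimulus
  set informative; the band's magnitude is consistent with the published
  per-trial optimality ceiling on the equal-probability subset (≈ 19
  points; the default generator's comes out near 22).
- **Trial order** is a seeded uniform shuffle; equal-probability trials are
  allocated 7 gain-only, 7 loss-only and 3 mixed; the distribution of the
  equal-probability trials over probability levels is left uniform. All of
  these are configurable rather than asserted as properties of the original
  instrument.

## The synthetic cohort

`simulate_cohort()` emulates the study conditions the analysis was designed
for: four groups — HC (n = 20), GAD (n = 15), SAD (n = 14), OCD (n = 10) —
with per-subject parameters drawn log-normally around group means
(log-scale SD 0.15 by default), guaranteeing positivity. Group means are
identical except that the OCD group's `alpha` is lowered (0.55 vs 0.85),
mirroring the one group difference the analysis is meant to detect without
asserting unpublished estimates. Clinical scores (PHQ-9, GAD-7, BDI, WSAS)
are drawn from normals truncated at zero with the published per-group
summary statistics as defaults, optionally sharing variance with a named
parameter's log-deviation at a requested correlation (used to exercise the
correlation analysis). Timeouts, when enabled, occur independently per
trial and carry no choice; the default rate is 0 because the original
frequency is unreported, and timeouts are excluded from likelihoods and
from the Delta-EV analysis.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: within-subject parameter drift, learning or
sequence effects, response-time structure, comorbidity structure among
clinical scales, and any misspecification of the CPT form itself. The
simulator draws choices from the exact model the estimator fits, so
recovery results are best-case.

## Estimation

`cpt_fit()` minimizes the negative log-likelihood over
`log(alpha), log(lam), log(gamma), log(delta)` with box bounds
`[log 0.05, log 20]` using `nlminb`, from a fixed multi-start schedule
(identity, conventional CPT magnitudes, box-corner mixes, then seeded
jitter; 8 starts by default). Log-parameterization enforces positivity;
multi-start addresses the mild multimodality we observe near the box
corners. Fits are deterministic given the settings seed and invariant to
trial order (records are sorted by trial id before the likelihood is
evaluated). A subject needs at least `min_trials = 50` usable trials to be
fitted — an identifiability safeguard, configurable.

The two-stage path (fit each subject, then run group statistics on the
estimates) is the primary inference route, matching an analysis in which
group comparisons are t-tests on estimated parameters.
`cpt_fit_hierarchical()` offers a penalized alternative in the spirit of a
nonlinear mixed-effects fit: per-subject log-parameters are shrunk toward
group fixed effects by Gaussian penalties, the penalized fits and group
means are updated by block coordinate descent, and each parameter's
random-effect SD is profiled on the coarse grid
`{0.025, 0.05, 0.1, 0.2, 0.4, 0.8}` (floored at the smallest point when the
between-subject dispersion degenerates). Group contrasts are parameterized
as a reference group plus additive log-scale dummy offsets, with Wald-type
tests built from the pooled within-group variance of the shrunken
per-subject estimates. This is a deliberate approximation to marginal
maximum likelihood — not a reimplementation of an nlme fit — and its
degrees of freedom are its own, not those of any published fit.

Numerical choices, collected: probability clipping at `1e-12`; the
weighting function evaluated in log space so `p^gamma` cannot underflow for
small `p`; convergence of the hierarchical sweep declared on a relative
objective change below `1e-3`; ties between equally good multi-starts
resolved by first occurrence (the schedule order is fixed).

## Group statistics

- `independent_t_test()` is the pooled-variance (Student) form, chosen so
  degrees of freedom follow the `n1 + n2 - 2` convention of the analyses it
  reproduces; Cohen's d uses the pooled SD.
- `one_sample_test_vs_one()` tests `lam` against 1 (no loss aversion);
  d is `(mean - 1) / sd`.
- `bonferroni()` and every test take the family size as an explicit
  argument; no corrected threshold is hard-coded anywhere, because the
  analyses being reproduced used different family sizes (12 parameter
  tests, 6 demographic tests, 16 correlations) and were not fully
  consistent about the resulting thresholds.
- `delta_ev_analysis()` restricts to the 14 equal-probability single-domain
  trials, where probability weighting is constant within a trial and loss
  aversion cannot separate the gambles, so departures from EV-optimality
  reflect value discrimination alone. `mixed_anova()` is the textbook
  between-within decomposition (group tested against subjects-within-
  groups; trial and interaction against the subject-by-trial residual) with
  listwise deletion of subjects missing any included trial; it is
  cross-checked against `stats::aov` with a subject error stratum in the
  test suite.

## Problem sizes used in validation

The test suite validates the pipeline at sizes chosen to make Monte-Carlo
conclusions stable while remaining desk-scale: parameter recovery uses one
subject at 2,016 trials (the 126-trial task repeated 16 times, ±10%
tolerance per parameter); the group sign-recovery property uses 20
replicates of an HC(20)-vs-OCD(10) cohort on the full task; family-wise
error calibration uses 200 null cohorts of 59 subjects on a reduced
42-trial task with a 2-start optimizer, trading per-fit polish for
replicate count (the estimates remain exchangeable across groups, which is
what a null calibration needs); the ΔEV symmetry check uses 10,000
simulated random choosers on the 14-trial analysis subset.

## Known limitations

- The hierarchical mode's Wald tests lean on shrunken estimates; their SEs
  are approximate and mildly anti-conservative when shrinkage is strong.
- With `k` fixed at 1 and utilities on the raw point scale, datasets
  simulated at identity parameters are nearly deterministic; estimation
  there relies on the minority of near-indifference trials, and tasks
  generated without the EV-gap band can be uninformative (see above).
- `alpha` is shared across domains; a per-domain curvature is not
  implemented, matching the restrictive model form the package reproduces.
- Equal-EV gamble pairs are excluded by construction, so the package never
  has to define optimal choice under a tie.
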