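---
title: "Modelling diagnostic delay in breast cancer: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diagnostic delay in breast cancer: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncodelay)
```

## The problem

Diagnostic delay — the interval between a patient first noticing a breast
symptom and receiving a definitive diagnosis — worsens breast-cancer
outcomes through several mechanisms at once: the tumour can advance a TNM
stage before treatment starts (stage migration), a later stage demands more
intensive treatment, and more intensive treatment carries more
complications. The size of these effects depends strongly on tumour
biology: triple-negative tumours progress much faster than hormone
receptor-positive ones, so a delay that is tolerable for one molecular
class is dangerous for another.

`oncodelay` implements the quantitative machinery for studying this
problem: a synthetic patient-level cohort generator, a five-state monthly
Markov cohort model with economic accumulation, cumulative stage-migration
curves with critical-delay thresholds and number-needed-to-treat, a causal
mediation decomposition over an explicit DAG, and Kaplan–Meier / Cox
survival summaries. Because the underlying hospital records are private,
the package is organised around two kinds of reproducibility:

1. **Exact reproduction** of every published summary number that is
   derivable from published inputs (category counts, per-category
   life-years lost, interval means, migration anchors, mediated
   proportions, the sample-size formula).
2. **Parameter recovery**: cohorts are simulated *from* the published
   parameters (hazard ratios, migration probabilities, path strengths) and
   the estimation machinery must recover those parameters from the
   simulated data.

## Delay taxonomy

Six delay bands are used everywhere: `<2w`, `2w–1m`, `1–2m`, `2–6m`,
`6–12m`, `≥1y`, with half-open day ranges `[0,14), [14,30), [30,60),
[60,180), [180,365), [365,730)`. Conversions are fixed at 1 month = 30
days and 1 year = 365 days; the open-ended `≥1y` band is truncated at 730
days (a two-year observation window is the plausible maximum for a
symptomatic cohort). The observed distribution over the bands is
(45, 84, 40, 241, 60, 169) of 639 symptomatic patients.

Each band also carries a fixed *representative day* — 0, 30, 60, 180, 270,
360 — at which migration curves are evaluated to build the per-category
grid. These are anchor-aligned month ends rather than band midpoints: with
them, the `2w–1m`, `2–6m` and `≥1y` grid columns land exactly on the
published 1-, 6- and 12-month anchor probabilities and the `6–12m` column
is the linear midpoint of the 6- and 12-month anchors, which is how the
published combined-assessment table was evidently constructed. Several
representative days therefore lie on or outside their own band's day range
by design.

## Synthetic cohort generator

`generate_cohort()` composes the sampling operations, fully seeded:

* **Delay**: category multinomial at the observed frequencies; day uniform
  (discrete) within the band.
* **Molecular class**: HR+ 0.60, HER2+ 0.25, triple-negative 0.15 by
  default. Only receptor *marginals* are published (75.5% ER+, 70.1% PR+,
  68.1% HER2−); the joint class mix is a package default chosen to be
  consistent with them and is configurable. Receptor flags are set to
  satisfy the class definitions exactly; Ki-67 high-expression rates per
  class (0.22/0.35/0.62) average to the published 31% marginal.
* **Baseline stage**: I 0.10, II 0.62, III 0.28 — from the published
  presenting-stage mix (10.1% stage IA/IB, 61.7% stage IIA/IIB, the rest
  stage III+).
* **Stage migration**: Bernoulli at the subtype curve evaluated at the
  patient's delay; a migration advances the stage by exactly one level
  (the published stage-transition probabilities parameterize single-step
  transitions only), so downstaging is impossible by construction.
* **Mediators**: treatment intensity is ordinal (surgery-only,
  surgery+chemo, multimodality) under a proportional-odds draw whose odds
  are multiplied by the published per-category gradient (1, 1.3, 1.7, 2.4,
  3.1, 3.8); the surgical-complication probability starts at 0.15 (85% of
  patients had no complication) with the same odds gradient.
* **Survival**: exponential with per-month rate
  `0.021 × HR(category)` — 0.021 is the published monthly death rate from
  the treated state, and the HR gradient is (1, 1.18, 1.27, 1.54, 1.92,
  2.35) — censored administratively at 120 months. The source states Cox
  modelling but no baseline distribution; the exponential matches the
  model's constant monthly rates.
* **System intervals**: referral/pathology/planning waits are gamma with
  means 23.2/14.7/18.5 days and shape 4 (coefficient of variation 0.5, a
  realistic skew for service waiting times; `Inf` gives degenerate
  intervals). Their means total 56.4 days.

What the generator does *not* emulate: correlation between subtype and
delay (in real data aggressive tumours may present faster), death before
diagnosis, competing mortality, informative censoring, and any association
between the mediators and survival *given* the delay category (survival is
driven by the category hazard gradient alone). Passing parameter-recovery
tests therefore shows the estimators are correct on data satisfying their
own assumptions — not that the published estimates are correct for the
real cohort.

```{r cohort}
cohort <- generate_cohort(cohort_config(n = 639, seed = 1))
table(cohort$delay_category)
```

## Markov cohort model

Five states: Symptomatic-Undiagnosed, Diagnosed-Untreated,
Treatment-Initiated, Progressive-Disease, Death (absorbing). Only the
published forward transitions exist; each row's diagonal is the complement
of its exits. Monthly cycle, 120-cycle horizon, membership counted at
cycle start (no half-cycle correction — the simplest convention, stated
and switchable by post-processing the trace), and the annual 3.5% discount
rate compounded exactly: `d(t) = 1.035^(−t/12)`, so the factor at 12
months is `1/1.035`.

Structural assumptions worth stating plainly:

* **No death exit from pre-treatment states.** The published transition
  set lists none, and the model carries that as-is. A consequence: in a
  counterfactual that only changes the diagnosis *rate*, slower diagnosis
  keeps more of the cohort in death-free states and so *increases* model
  life-years at the horizon. The harms of delay enter through the
  hazard-ratio gradient and stage migration, not through the
  diagnosis-speed stratum.
* **Stratified probabilities are sparse.** A stratified value overrides
  the overall one only where the source lists it; otherwise the overall
  value applies (`build_matrix()`'s fallback). The diagnosis-rate values
  by time interval are non-monotone in the source (0.937 for 1–2 months
  vs 0.623 for 2–6 months) and are carried verbatim.
* **Costs.** Phase costs are published without an accrual rule. The
  package applies diagnostic (2,450 SAR), initial-treatment
  (15,300–42,800 SAR, linear in stage I→IV), progressive-disease (18,700
  SAR) and terminal-care (23,500 SAR) amounts per state-*entry* event, and
  continuing care (4,200 SAR) per month of Treatment-Initiated occupancy.
  These choices affect only the cost column.

`mle_transitions()` calibrates monthly probabilities as transition counts
over person-months at risk; states with zero exposure produce *missing*
entries (not zeros), which the matrix builder resolves by fallback.
`microsim()` is the Monte-Carlo oracle: the deterministic trace must agree
with 200,000 simulated paths within 3 binomial standard errors at every
cycle, and re-estimating from the simulated histories must recover the
generating matrix.

```{r markov}
m <- build_matrix()
tr <- run_trace(m, cycles = 120)
accumulate(tr, economic_params(), matrix = m)
```

## Migration curves and critical thresholds

Curves pass through (0, 0) and the published 1/3/6/12-month cumulative
probabilities. The source says intermediate values were "interpolated"
without naming a scheme; the default is piecewise-linear in days, which
reproduces the published 9-month (6–12m column) cells within half a
percentage point (exactly for the Stage I→II and III→IV rows), and a
geometric per-month alternative `p(d) = 1 − (1 − p₁)^(d/30)` is available
behind the `scheme` argument. The critical threshold is the smallest
integer day at which the curve reaches 10% (day-by-day scan; "exceeds"
read as ≥); NNT is `ceiling(1/ARR)` — fractional patients are meaningless,
so the ceiling convention applies.

The published thresholds themselves (38/52/85 days for
triple-negative/HER2+/HR+; 56/68/73 for the stage transitions — and a
second, different stage set, 78/92/115, in the combined table) are **not
derivable** from the published anchors under either scheme: linear
interpolation puts the triple-negative curve at 10% on day 57, geometric
on day 59, against a published 38. Interestingly, linear interpolation
*does* give day 78 for Stage I→II, matching the combined table. The
published NNTs equal `ceiling(1/p)` at the 3-month anchor for two of the
three stage rows (9 and 13) but not the third (14 vs computed 18); the
ARR definition behind them is unstated. The package therefore carries all
published thresholds and NNTs as labelled reference constants and reports
its computed values alongside (`threshold_report()`), asserting agreement
for neither.

```{r thresholds}
threshold_report()
```

## Causal diagram and mediation

The study diagram (`study_dag()`) has delay affecting survival directly
and through stage migration, treatment intensity and complications, with
age, BMI, comorbidity, family history and subtype confounding both delay
and survival. `backdoor_sets()` enumerates every inclusion-minimal
adjustment set satisfying the backdoor criterion, verified by
d-separation (moralized ancestral graph); the test suite checks it
against an independent path-enumeration oracle. Ties in enumeration are
resolved by lexicographic order so output is deterministic.

The mediation decomposition uses the product method on a **linear working
model of the log-hazard scale**: the source never states its regression
forms, so this scale is a documented package choice, and `rate_transform()`
(`−log T`, whose expectation is `log λ + γ` for exponential times)
provides the outcome proxy for survival data. For mediator *k*, `a_k` is
the marginal exposure→mediator slope and `b_k` the mediator's coefficient
in the joint outcome model; by the omitted-variable-bias identity of least
squares, `total = direct + Σ a_k·b_k` holds *exactly* in every sample, so
the additivity invariant is machine-precision, not asymptotic. Because
`a_k` is the *total* exposure→mediator effect, effects routed through an
upstream mediator's influence on a downstream one are attributed to the
downstream (last) mediator, and the estimator is identical whether the
mediators are treated as causally ordered (stage → treatment →
complications) or parallel — which is why no separate "parallel mode"
switch exists. Confidence intervals are percentile bootstrap (B = 1,000 by
default; BCa adds complexity without changing coverage materially at
these sample sizes). Two caveats are attached to every printed
decomposition: hazard-ratio effects are non-collapsible across the linear
working scale, and a total effect at machine zero makes proportions
undefined (an error, not a silent division).

`simulate_mediation_cohort()` generates exposure, three ordered
binary/ordinal mediators and a linear outcome whose path products are
calibrated so the expected mediated shares are 67.3% / 18.9% / 7.4% with a
6.4% direct remainder; `decompose()` must recover these within its
bootstrap interval.

```{r mediation}
dec <- decompose(simulate_mediation_cohort(5000, seed = 3),
                 "delay_exposure",
                 c("stage_migration", "treatment_intensity", "complication"),
                 "outcome", n_boot = 200, seed = 4)
round(dec$proportions, 3)
```

## Survival metrics

Kaplan–Meier estimation and Cox partial-likelihood fitting are delegated
to the `survival` package with **Breslow** tie handling (simulated times
are continuous, so the tie correction is immaterial and the simpler rule
is preferred). Life-years lost is the restricted-mean survival-time
difference between the reference and exposed curves by exact step
integration over the 120-month horizon — the same timescale as the Markov
trace. Note the published per-category LYL values (0.7 … 6.7 years)
exceed what the published hazard ratios can produce over a 10-year
restricted horizon (the simulated `≥1y` arm loses about 2.0 years); how
they were computed is unstated, so they are carried as reference
constants, used only in the count-weighted average (3.40 years), and never
presented as recomputed. The published QALY-loss column exceeds the LYL
column despite sub-unit utilities and is likewise carried verbatim.

The validation statistics (Hosmer–Lemeshow over 10 equal-count deciles
with `bins − 2` degrees of freedom, concordance over comparable pairs,
MAPE over nonzero observations, RMSE) are implemented as formulas and
property-tested (perfect predictions, hand-computed cases, null
calibration); their published values require the original patient data
and are out of reach by design.

## Numerical and degenerate-input choices

* Probability vectors must sum to 1 within 1e−12; exit-probability rows
  above 1 are rejected naming the state.
* The high-risk percentage truncates (not rounds) its final decimal:
  470/639 = 73.55…%, printed as 73.5% in the source. The unrounded value
  rides along as an attribute. The source also attributes the same
  percentage to 589/802; the report bundle emits both denominators with
  labels rather than choosing.
* Cochran's `n = z²p(1−p)/d²` is floored (384 at z = 1.96, p = 0.5,
  d = 0.05).
* Empty migration-anchor sets give a curve identically zero; curves that
  never reach the threshold level return `NA` rather than a sentinel day.
* All randomness flows from explicit seeds; bootstrap and
  microsimulation results are bit-reproducible given the seed.

## Problem sizes

The package's own test and analysis runs use: 639–20,000-patient
cohorts (20,000 for parameter recovery of the hazard gradient and the
mediated shares, matching the precision at which the published CIs are
informative), 200,000 microsimulation paths for the trace-equivalence
check, 50,000–100,000 draws for distributional checks at 3 standard
errors, and B = 1,000 bootstrap replications for reported intervals
(smaller B only where a test checks reproducibility rather than
coverage).

## Known limitations

* The cohort generator is marginal-faithful, not joint-faithful: it
  reproduces published marginals and gradients but invents independence
  where the joint structure is unpublished.
* The mediation working scale is linear; no exposure–mediator
  interactions, natural-effect estimands, or unmeasured-confounding
  sensitivity analyses are provided.
* The Markov model has no tunnel states, so transition probabilities
  cannot depend on time-in-state; probabilistic sensitivity analysis over
  the economic parameters is out of scope.
* Published critical thresholds and the LYL/QALY-loss columns are
  reference constants, not reproducible quantities; every table that
  shows them also shows what the package computes from the published
  anchors.
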