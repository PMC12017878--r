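# oncodelay

Causal and Markov modelling of diagnostic delay in symptomatic breast
cancer.

Diagnostic delay — the time from first symptom recognition to definitive
diagnosis — lets a tumour advance a TNM stage before treatment begins, and
how fast that happens depends on molecular biology: triple-negative
tumours upstage far sooner than hormone receptor-positive ones. This
package implements, as tested and reusable R functions, the full analysis
chain for quantifying that process when the patient-level records
themselves are private:

* a **seeded synthetic cohort generator** reproducing the observed
  six-band delay distribution (45/84/40/241/60/169 of 639 symptomatic
  patients), molecular-class and stage mixes, delay-dependent stage
  migration, delay-dependent treatment-intensity and complication
  mediators, and exponential proportional-hazards survival with the
  published hazard gradient HR = (1, 1.18, 1.27, 1.54, 1.92, 2.35),
  censored at 120 months;
* a **five-state monthly Markov cohort model**
  (Symptomatic-Undiagnosed → Diagnosed-Untreated → Treatment-Initiated →
  Progressive-Disease → Death) with maximum-likelihood transition
  calibration, cohort traces `x_t = x_{t-1} P`, and discounted life-years,
  QALYs and costs with `d(t) = 1.035^{-t/12}`;
* **stage-migration curves** through the published 1/3/6/12-month anchors
  with critical-delay thresholds (smallest day at which cumulative
  migration risk reaches 10%) and `NNT = ⌈1/ARR⌉`;
* **product-method causal mediation** on a linear log-hazard working
  scale — indirect effect through mediator *k* is `a_k · b_k`, direct
  effect the exact remainder — with percentile bootstrap CIs (B = 1,000),
  over an explicit DAG with minimal backdoor adjustment-set search;
* **Kaplan–Meier / Cox** summaries (Breslow ties), RMST-based life-years
  lost, and Hosmer–Lemeshow / concordance / MAPE / RMSE calibration
  formulas.

## Worked example

```r
library(oncodelay)

# a seeded cohort at the study's conditions
cohort <- generate_cohort(cohort_config(n = 20000, seed = 5))

# Cox partial likelihood recovers the generating hazard gradient
fit <- ph_fit(cohort, "delay_category")
fit[fit$term == "delay_category>=1y", c("hr", "hr_low", "hr_high")]
#>         hr   hr_low  hr_high
#> 5 2.287053 2.150436 2.432349      # generating value: 2.35

# critical thresholds: computed from the anchors vs published constants
threshold_report()[5, c("group", "threshold_linear_days",
                        "threshold_printed_days")]
#>            group threshold_linear_days threshold_printed_days
#> 5 TripleNegative                    57                     38

# mediation decomposition on a path-calibrated cohort
dec <- decompose(simulate_mediation_cohort(20000, seed = 11),
                 "delay_exposure",
                 c("stage_migration", "treatment_intensity", "complication"),
                 "outcome", n_boot = 1000, seed = 12)
round(dec$proportions, 3)
#>     stage_migration treatment_intensity        complication              direct
#>               0.679               0.187               0.078               0.056
# generating shares: 0.673 / 0.189 / 0.074 / 0.064

# summaries derivable exactly from published inputs
weighted_average_lyl()                 # 3.40 life-years lost per patient
high_risk_fraction()                   # 73.5 (% with delay > 2 months)
total_system_delay(c(23.2, 14.7, 18.5))  # 56.4 days
cochran_n(1.96, 0.5, 0.05)             # 384
residual_direct(c(0.673, 0.189, 0.074))  # 0.064
```

The recovered `≥1y` hazard ratio (here 2.29, 95% CI 2.15–2.43) is a
stochastic estimate whose CI covers the generating value 2.35; the
mediated-share estimates recover the generating 67.3/18.9/7.4/6.4%
decomposition; the last five numbers are exact arithmetic on published
inputs.

## Analysis workflow

The numbered scripts under `analysis/` run the full study pipeline and
write their tables under `results/`:

| script | does |
|---|---|
| `01_simulate_cohort.R` | cohort + system-interval simulation, composition summary |
| `02_markov_model.R` | traces, subtype economics, ML recalibration, counterfactual |
| `03_migration_thresholds.R` | migration grid, thresholds, NNTs vs published constants |
| `04_mediation.R` | backdoor sets, bootstrap mediation decomposition |
| `05_survival.R` | Cox gradient recovery, KM curves, RMST life-years lost |
| `06_report.R` | end-to-end `run_pipeline()` bundle with provenance keys |

Run them from the repository root, e.g. `Rscript analysis/01_simulate_cohort.R`.

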