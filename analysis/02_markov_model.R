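#!/usr/bin/env Rscript
# Five-state monthly Markov cohort model: overall and stratified traces,
# maximum-likelihood recalibration from microsimulated histories, and
# discounted economic outcomes, including a delay-interval counterfactual.

suppressMessages(library(oncodelay))
dir.create("results", showWarnings = FALSE)

tab <- default_transition_table()
econ <- economic_params()
overall <- build_matrix(tab)
trace <- run_trace(overall, cycles = econ$horizon)
write_trace(trace, "results/cohort_trace.csv")
out <- accumulate(trace, econ, matrix = overall)
cat(sprintf("Overall stratum over 10 years: %.2f discounted life-years, %.2f QALYs, %.0f SAR\n",
            out$life_years, out$qalys, out$discounted_cost))

# stratified economic outcomes by molecular subtype
econ_rows <- lapply(c("HR+", "HER2+", "TripleNegative"), function(s) {
  m <- build_matrix(tab, c("Molecular Subtype" = s))
  tr <- run_trace(m, cycles = econ$horizon)
  acc <- accumulate(tr, econ, matrix = m)
  data.frame(stratum = s, life_years = round(acc$life_years, 3),
             qalys = round(acc$qalys, 3),
             cost_sar = round(acc$discounted_cost),
             death_at_horizon = round(tr$occupancy[econ$horizon + 1, "Death"], 4))
})
econ_tab <- do.call(rbind, econ_rows)
utils::write.csv(econ_tab, "results/economics_by_subtype.csv",
                 row.names = FALSE)
print(econ_tab, row.names = FALSE)

# parameter recovery: microsimulate histories, re-estimate by ML
sim <- microsim(overall, n = 50000, cycles = 60, seed = 3)
fit <- mle_transitions(sim)
fit$generating <- apply(fit, 1, function(r) overall[r[["from"]], r[["to"]]])
write_transition_table(fit, "results/transition_fit.csv")
cat(sprintf("ML recalibration: max |estimate - generating| = %.4f over %d transitions\n",
            max(abs(fit$probability - fit$generating)), nrow(fit)))

# counterfactual: fast (<2 weeks) vs delayed (2-6 months) diagnosis stratum
cf <- counterfactual(tab,
                     scenario_a = list(stratum = c("Time Interval" = "2-6m")),
                     scenario_b = list(stratum = c("Time Interval" = "<2w")),
                     econ = econ)
cat(sprintf("Counterfactual (2-6m minus <2w diagnosis-rate stratum): %+.3f life-years, %+.4f death probability at horizon\n",
            cf$delta$life_years, cf$delta$death_prob))
cat("Note: pre-treatment states carry no death exit, so slower diagnosis\n")
cat("defers treated-state mortality within the model horizon; delay harms\n")
cat("enter through the hazard-ratio gradient and stage migration instead.\n")
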