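#!/usr/bin/env Rscript
# Causal structure and mediation: backdoor adjustment sets on the study
# diagram, then the product-method decomposition with a 1,000-replication
# percentile bootstrap on a cohort generated with the published path
# strengths (67.3 / 18.9 / 7.4 / 6.4% of the total effect).

suppressMessages(library(oncodelay))
dir.create("results", showWarnings = FALSE)

g <- study_dag()
sets <- backdoor_sets(g, "delay", "survival")
cat("Minimal sufficient adjustment set(s) for delay -> survival:\n")
for (s in sets) cat("  {", paste(s, collapse = ", "), "}\n")

cohort <- simulate_mediation_cohort(20000, seed = 11)
dec <- decompose(cohort, "delay_exposure",
                 c("stage_migration", "treatment_intensity", "complication"),
                 "outcome", n_boot = 1000, seed = 12)
print(dec)

paths <- names(dec$proportions)
tab <- data.frame(
  pathway = paths,
  proportion_pct = round(100 * unname(dec$proportions), 1),
  ci_low_pct = round(100 * dec$ci[paste0("prop_", paths), 1], 1),
  ci_high_pct = round(100 * dec$ci[paste0("prop_", paths), 2], 1),
  published_pct = c(67.3, 18.9, 7.4, 6.4)
)
utils::write.csv(tab, "results/mediation_decomposition.csv",
                 row.names = FALSE)
jsonlite::write_json(
  list(effects = as.list(dec$effects),
       proportions = as.list(dec$proportions),
       ci = as.data.frame(dec$ci), n_boot = dec$n_boot, seed = dec$seed),
  "results/mediation.json", auto_unbox = TRUE, digits = NA)
cat("\nResidual direct share from the published mediated proportions:",
    sprintf("%.1f%%\n", 100 * residual_direct(c(0.673, 0.189, 0.074))))
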