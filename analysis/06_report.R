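#!/usr/bin/env Rscript
# End-to-end pipeline run: regenerates every stage from one seeded config
# and writes the full report bundle, closing with the summary numbers that
# are derivable from published inputs.

suppressMessages(library(oncodelay))

bundle <- run_pipeline(cohort_config(n = 10000, seed = 31), n_boot = 500,
                       out_dir = "results/report")

cat("Report bundle written to results/report/\n")
cat(sprintf("Config hash: %s (seed %d, n = %d)\n",
            bundle$metadata$config_hash, bundle$metadata$seed,
            bundle$metadata$n))
cat("\nHeadline quantities:\n")
cat(sprintf("  Count-weighted average life-years lost: %.2f\n",
            bundle$weighted_lyl$value))
cat(sprintf("  High-risk delay share (symptomatic denominator 639): %.1f%%\n",
            as.numeric(bundle$high_risk_pct$value)))
cat(sprintf("  High-risk delay share (cohort denominator 802): %.1f%%\n",
            as.numeric(bundle$high_risk_pct_cohort_denominator$value)))
cat(sprintf("  Cumulative mean system delay: %.1f days\n",
            bundle$system_delay_days$value))
cat(sprintf("  Cochran minimum sample size (z=1.96, p=0.5, d=0.05): %d\n",
            bundle$sample_size$value))
cat(sprintf("  Stage-migration share of the total effect (path-calibrated): %.1f%%\n",
            100 * bundle$mediation$proportions[["stage_migration"]]))
cat(sprintf("  Same share in the patient cohort itself: %.1f%% (near-null by construction)\n",
            100 * bundle$cohort_mediation$proportions[["stage_migration"]]))
hr <- bundle$survival_fit
cat(sprintf("  Recovered >=1y hazard ratio: %.2f\n",
            hr$hr[hr$term == "delay_category>=1y"]))
cat(sprintf("  Discounted life-years over 10 years (overall stratum): %.2f\n",
            bundle$economics$value$life_years))
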