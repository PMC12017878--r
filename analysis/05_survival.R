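#!/usr/bin/env Rscript
# Survival analysis on a large synthetic cohort: Cox partial-likelihood
# recovery of the per-category hazard gradient, Kaplan-Meier curves,
# restricted-mean life-years lost versus the reference category, and the
# published weighted-average life-years lost.

suppressMessages(library(oncodelay))
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(cohort_config(n = 20000, seed = 21))
fit <- ph_fit(cohort, "delay_category")
ref <- delay_reference_table()
fit_tab <- data.frame(
  term = fit$term,
  hr = round(fit$hr, 3),
  ci = sprintf("(%.2f-%.2f)", fit$hr_low, fit$hr_high),
  published_hr = ref$hr[-1]
)
utils::write.csv(fit_tab, "results/cox_fit.csv", row.names = FALSE)
cat("Recovered vs published hazard ratios:\n")
print(fit_tab, row.names = FALSE)

# KM curves and RMST-based life-years lost per category over 120 months
cats <- levels(cohort$delay_category)
km_ref <- with(cohort[cohort$delay_category == "<2w", ],
               km_estimate(time_months, event))
lyl_rows <- lapply(cats, function(cl) {
  sub <- cohort[cohort$delay_category == cl, ]
  km <- km_estimate(sub$time_months, sub$event)
  write_km(km, file.path("results", sprintf("km_%s.csv",
                                            gsub("[^0-9A-Za-z]", "_", cl))))
  data.frame(delay_category = cl,
             median_months = round(km$time[which(km$survival <= 0.5)[1]], 1),
             lyl_simulated = round(life_years_lost(km_ref, km, 120), 2))
})
lyl_tab <- do.call(rbind, lyl_rows)
lyl_tab$lyl_published = ref$lyl_years
utils::write.csv(lyl_tab, "results/life_years_lost.csv", row.names = FALSE)
cat("\nRMST life-years lost vs the <2w reference (120-month horizon):\n")
print(lyl_tab, row.names = FALSE)
cat("\nThe published per-category LYL (up to 6.7 years) exceed what the\n")
cat("published hazard ratios imply over the 10-year horizon; they are\n")
cat("carried as reference constants in the weighted summary below.\n")
cat(sprintf("Count-weighted average of the published LYL values: %.2f years\n",
            weighted_average_lyl()))

# calibration statistics of a 24-month mortality risk model on the cohort
p24 <- 1 - exp(-cohort_config()$baseline_hazard *
                 cohort_config()$hr_by_category[cohort$delay_category] * 24)
died24 <- as.integer(cohort$time_months <= 24 & cohort$event == 1)
vs <- validation_stats(p24, died24, p24, died24)
cat(sprintf("\n24-month risk model on the synthetic cohort: HL p = %.2f, C-statistic = %.3f, MAPE and RMSE vs outcomes: %.1f%% / %.3f\n",
            vs$hosmer_lemeshow$p_value, vs$c_statistic, vs$mape, vs$rmse))
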