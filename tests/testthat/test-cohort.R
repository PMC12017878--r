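# Synthetic cohort generator: sampling distributions, invariants,
# determinism.

test_that("delay sampling follows the configured distribution", {
  cfg <- cohort_config(seed = 1)
  set.seed(101)
  # degenerate distribution pins the category and its day range
  degen <- cohort_config(delay_probs = c(1, 0, 0, 0, 0, 0))
  d <- sample_delay(degen, 500)
  expect_true(all(d$delay_category == "<2w"))
  expect_true(all(d$delay_days >= 0 & d$delay_days < 14))

  n <- 100000
  d <- sample_delay(cfg, n)
  freq <- table(factor(d$delay_category, levels = delay_categories()$label)) / n
  for (k in seq_len(6)) {
    p <- cfg$delay_probs[k]
    expect_within_3se(freq[[k]], p, sqrt(p * (1 - p) / n),
                      label = names(cfg$delay_probs)[k])
  }
  # uniform day within 2-6m: mean of discrete uniform over 60..179 is 119.5
  days <- d$delay_days[d$delay_category == "2-6m"]
  expect_true(all(days >= 60 & days < 180))
  expect_within_3se(mean(days), 119.5, stats::sd(days) / sqrt(length(days)),
                    label = "mean 2-6m day")
})

test_that("delay sampling rejects invalid probability vectors", {
  expect_error(cohort_config(delay_probs = c(0.5, 0.2, 0.1, 0.1, 0.05, 0.1)),
               "sum to 1")
  expect_error(cohort_config(delay_probs = c(-0.1, 0.3, 0.2, 0.2, 0.2, 0.2)),
               "nonnegative")
})

test_that("subtype assignment respects class definitions and frequencies", {
  set.seed(7)
  only_hr <- assign_subtype(cohort_config(subtype_probs = c(1, 0, 0)), 200)
  expect_true(all(only_hr$molecular_class == "HR+"))
  expect_true(all(only_hr$her2 == 0) && all(only_hr$er == 1 | only_hr$pr == 1))
  only_tn <- assign_subtype(cohort_config(subtype_probs = c(0, 0, 1)), 200)
  expect_true(all(only_tn$er == 0 & only_tn$pr == 0 & only_tn$her2 == 0))

  n <- 100000
  s <- assign_subtype(cohort_config(), n)
  # class flags consistent everywhere
  tn <- s$molecular_class == "TripleNegative"
  expect_identical(tn, s$er == 0 & s$pr == 0 & s$her2 == 0)
  expect_identical(s$molecular_class == "HER2+", s$her2 == 1)
  for (cls in c("HR+", "HER2+", "TripleNegative")) {
    p <- cohort_config()$subtype_probs[[cls]]
    expect_within_3se(mean(s$molecular_class == cls), p,
                      sqrt(p * (1 - p) / n), label = cls)
  }
})

test_that("stage migration follows the subtype curve and only upstages", {
  set.seed(21)
  n <- 100000
  # zero delay: curve anchored at the origin, stage unchanged
  m0 <- simulate_migration(rep("I", 100), rep("TripleNegative", 100),
                           rep(0L, 100))
  expect_true(all(m0$migrated == 0) && all(m0$stage_at_dx == "I"))

  m_tn <- simulate_migration(rep("I", n), rep("TripleNegative", n),
                             rep(360L, n))
  expect_within_3se(mean(m_tn$migrated), 0.536, sqrt(0.536 * 0.464 / n),
                    label = "TN migration at 12 months")
  m_hr <- simulate_migration(rep("II", n), rep("HR+", n), rep(30L, n))
  expect_within_3se(mean(m_hr$migrated), 0.021, sqrt(0.021 * 0.979 / n),
                    label = "HR+ migration at 1 month")
  # single-step advancement only
  expect_true(all(m_tn$stage_at_dx %in% c("I", "II")))
  expect_error(simulate_migration("I", "Unknown", 30), "no migration curve")
})

test_that("survival times are exponential proportional hazards with censoring", {
  cfg <- cohort_config()
  set.seed(33)
  n <- 100000
  s <- simulate_survival(rep("<2w", n), cfg)
  expect_true(all(s$time_months <= 120))
  expect_true(all(s$event[s$time_months < 120] == 1))
  # exponential median ln(2)/0.021 = 33.0 months
  med <- stats::median(s$time_months)
  expect_lt(abs(med - log(2) / 0.021), 0.7)
  expect_error(simulate_survival("<2w", cohort_config(baseline_hazard = -1)),
               "positive")
})

test_that("generate_cohort is seed-deterministic and reproduces its marginals", {
  cfg <- cohort_config(n = 639, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n = 639, seed = 100))
  expect_false(identical(a, c2))

  counts <- table(a$delay_category)
  expected <- c(45, 84, 40, 241, 60, 169)
  for (k in seq_len(6)) {
    p <- expected[k] / 639
    expect_within_3se(counts[[k]] / 639, p, sqrt(p * (1 - p) / 639),
                      label = paste("count", names(counts)[k]))
  }
  # invariants on every record
  cats <- delay_categories()
  idx <- match(as.character(a$delay_category), cats$label)
  expect_true(all(a$delay_days >= cats$lower_day[idx] &
                    a$delay_days < cats$upper_day[idx]))
  expect_true(all(match(a$stage_at_dx, c("I", "II", "III", "IV")) >=
                    match(a$baseline_stage, c("I", "II", "III", "IV"))))
  expect_identical(a$migrated == 1, a$stage_at_dx != a$baseline_stage)
  expect_true(all(a$time_months <= 120))

  big <- generate_cohort(cohort_config(n = 10000, seed = 17))
  p_hr <- 0.735524
  expect_within_3se(mean(big$delay_days > 60), p_hr,
                    sqrt(p_hr * (1 - p_hr) / 10000),
                    label = "high-risk fraction")
  expect_error(generate_cohort(cohort_config(n = 0)), "positive")
})

test_that("mediators are delay-dependent in the expected direction", {
  co <- generate_cohort(cohort_config(n = 20000, seed = 3))
  mean_int <- tapply(co$treatment_intensity, co$delay_category, mean)
  expect_lt(mean_int[["<2w"]], mean_int[[">=1y"]])
  comp <- tapply(co$complication, co$delay_category, mean)
  expect_lt(comp[["<2w"]], comp[[">=1y"]])
})

test_that("system intervals have the configured means and validate input", {
  degen <- cohort_config(system_interval_shape = Inf)
  si <- generate_system_intervals(degen, 5)
  expect_equal(unique(si$referral), 23.2)
  expect_equal(unique(si$total), 56.4)

  set.seed(4)
  n <- 100000
  si <- generate_system_intervals(cohort_config(), n)
  se_total <- stats::sd(si$total) / sqrt(n)
  expect_within_3se(mean(si$total), 56.4, se_total, label = "mean total delay")
  expect_error(cohort_config(system_interval_means = c(-1, 10, 10)),
               "positive")
})

test_that("cohort CSV round trip preserves the table", {
  co <- generate_cohort(cohort_config(n = 50, seed = 8))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$delay_category, co$delay_category)
  expect_equal(back$time_months, co$time_months, tolerance = 1e-12)
  unlink(path)
})

test_that("configs load from YAML with a mandatory seed", {
  path <- system.file("extdata", "default_config.yaml", package = "oncodelay")
  cfg <- read_config(path)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n, 639L)
  noseed <- tempfile(fileext = ".yaml")
  writeLines("n: 10", noseed)
  expect_error(read_config(noseed), "seed")
  unlink(noseed)
})
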