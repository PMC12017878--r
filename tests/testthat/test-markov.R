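# Markov engine: matrix construction, trace propagation, MLE calibration,
# economic accumulation, counterfactuals, microsimulation.

test_that("build_matrix reproduces the published overall structure", {
  m <- build_matrix()
  expect_equal(m["Symptomatic-Undiagnosed", "Diagnosed-Untreated"], 0.302)
  expect_equal(m["Symptomatic-Undiagnosed", "Symptomatic-Undiagnosed"], 0.698)
  expect_equal(unname(m["Death", ]), c(0, 0, 0, 0, 1))
  expect_equal(unname(rowSums(m)), rep(1, 5))
  # no death exit from the pre-treatment states (structural assumption)
  expect_equal(m["Diagnosed-Untreated", "Death"], 0)
  expect_equal(m["Symptomatic-Undiagnosed", "Death"], 0)
})

test_that("build_matrix applies stratified values with Overall fallback", {
  tab <- default_transition_table()
  m <- build_matrix(tab, c("Molecular Subtype" = "TripleNegative"))
  expect_equal(m["Treatment-Initiated", "Progressive-Disease"], 0.138)
  # transitions without a stratified row fall back to Overall
  expect_equal(m["Symptomatic-Undiagnosed", "Diagnosed-Untreated"], 0.302)
  m2 <- build_matrix(tab, c("Time Interval" = "2-6m"))
  expect_equal(m2["Symptomatic-Undiagnosed", "Diagnosed-Untreated"], 0.623)

  bad <- tab
  bad$probability[bad$from == "Treatment-Initiated" &
                    bad$stratum_key == "Overall"] <- 0.6
  expect_error(build_matrix(bad), "exceed 1")
})

test_that("run_trace conserves mass, absorbs into Death and matches one-step values", {
  m <- build_matrix()
  tr <- run_trace(m, cycles = 120)
  expect_equal(tr$occupancy["1", "Diagnosed-Untreated"], 0.302)
  expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-12))
  expect_true(all(diff(tr$occupancy[, "Death"]) >= -1e-15))
  # trace equals the matrix-power computation
  p60 <- c(1, 0, 0, 0, 0)
  mm <- diag(5)
  for (i in 1:60) mm <- mm %*% m
  expect_equal(unname(tr$occupancy["60", ]), unname(p60 %*% mm)[1, ],
               tolerance = 1e-12)
  # expected start-of-cycle months in the symptomatic state: geometric 1/0.302
  tr_long <- run_trace(m, cycles = 600)
  expect_equal(sum(tr_long$occupancy[, "Symptomatic-Undiagnosed"]), 1 / 0.302,
               tolerance = 1e-6)
  expect_error(run_trace(m, initial_occupancy = c(0.5, 0, 0, 0, 0)),
               "sum to 1")
})

test_that("microsimulation agrees with the deterministic trace", {
  m <- build_matrix()
  sim <- microsim(m, n = 20000, cycles = 60, seed = 42)
  tr <- run_trace(m, cycles = 60)
  se <- pmax(sim$se, 1e-4)
  expect_true(all(abs(sim$occupancy - tr$occupancy[, colnames(sim$occupancy)])
                  <= 3 * se + 1e-12))
  # determinism and single-path validity
  sim2 <- microsim(m, n = 20000, cycles = 60, seed = 42)
  expect_identical(sim$paths, sim2$paths)
  one <- microsim(m, n = 1, cycles = 30, seed = 1)
  expect_true(all(one$paths %in% health_states()))
  final <- one$paths[1, 31]
  expect_true(final %in% health_states())
})

test_that("mle_transitions recovers a known generating matrix", {
  # direct count ratio: 30 exits in 100 person-months at risk
  h <- rbind(
    matrix(rep(c("A", "A"), 35), ncol = 2, byrow = TRUE),
    matrix(rep(c("A", "B"), 30), ncol = 2, byrow = TRUE),
    matrix(rep(c("A", "A"), 35), ncol = 2, byrow = TRUE)
  )
  est <- mle_transitions(h)
  expect_equal(est$probability[est$from == "A" & est$to == "B"], 0.30)

  m <- build_matrix()
  sim <- microsim(m, n = 5000, cycles = 60, seed = 13)
  est <- mle_transitions(sim)
  for (r in seq_len(nrow(est))) {
    truth <- m[est$from[r], est$to[r]]
    # binomial SE from the person-months actually at risk
    risk <- sum(sim$paths[, -ncol(sim$paths)] == est$from[r])
    expect_within_3se(est$probability[r], truth,
                      sqrt(max(truth * (1 - truth), 1e-6) / risk),
                      label = paste(est$from[r], "->", est$to[r]))
  }
  # a state never visited yields no rows; build_matrix falls back to Overall
  absorbed <- matrix("Death", 10, 5)
  est0 <- mle_transitions(absorbed)
  expect_equal(nrow(est0), 0)
  expect_error(mle_transitions(matrix(character(0), 0, 0)), "at least two")
})

test_that("accumulate computes discounted life-years, QALYs and costs", {
  # one alive state, utility 1, zero discount, 12 cycles: exactly 1 life-year
  m <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("Alive", "Death"), c("Alive", "Death")))
  tr <- run_trace(m, c(1, 0), cycles = 12)
  econ <- economic_params(discount_rate = 0, horizon = 12,
                          utilities = c(Alive = 1, Death = 0))
  out <- accumulate(tr, econ)
  expect_equal(out$life_years, 1.0)
  expect_equal(out$qalys, 1.0)

  # discount factor compounds the annual rate exactly
  expect_equal(discount_factor(12), 1 / 1.035)
  expect_equal(discount_factor(0), 1)

  # one cycle fully in Progressive-Disease contributes 0.45/12 QALYs
  m5 <- build_matrix()
  occ0 <- c(0, 0, 0, 1, 0)
  tr5 <- run_trace(m5, occ0, cycles = 1)
  econ1 <- economic_params(discount_rate = 0, horizon = 1)
  expect_equal(accumulate(tr5, econ1)$qalys, 0.45 / 12)

  # discounted quantities never exceed undiscounted ones
  tr120 <- run_trace(m5, cycles = 120)
  disc <- accumulate(tr120, economic_params())
  undisc <- accumulate(tr120, economic_params(discount_rate = 0))
  expect_lt(disc$life_years, undisc$life_years)
  expect_lt(disc$qalys, undisc$qalys)
  expect_error(accumulate(tr120, economic_params(horizon = 60)), "mismatch")
})

test_that("toy two-state chain matches the closed-form absorption sums", {
  p_exit <- 0.3
  m <- matrix(c(1 - p_exit, p_exit, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("Alive", "Death"), c("Alive", "Death")))
  cycles <- 24
  tr <- run_trace(m, c(1, 0), cycles = cycles)
  expect_equal(unname(tr$occupancy[, "Alive"]), (1 - p_exit)^(0:cycles))
  econ <- economic_params(discount_rate = 0, horizon = cycles,
                          utilities = c(Alive = 1, Death = 0))
  ly_closed <- (1 - (1 - p_exit)^cycles) / p_exit / 12
  expect_equal(accumulate(tr, econ)$life_years, ly_closed, tolerance = 1e-12)
})

test_that("counterfactual scenarios report outcome deltas", {
  econ <- economic_params()
  same <- counterfactual(scenario_a = list(stratum = NULL),
                         scenario_b = list(stratum = NULL), econ = econ)
  expect_equal(same$delta$life_years, 0)
  expect_equal(same$delta$death_prob, 0)

  # slower diagnosis (2-6m) delays exposure to treated-state mortality, so
  # the model assigns it more life-years at the fixed horizon
  curves <- default_migration_curves()
  cf <- counterfactual(
    scenario_a = list(stratum = c("Time Interval" = "2-6m"),
                      curve = curves$TripleNegative, delay_days = 120),
    scenario_b = list(stratum = c("Time Interval" = "<2w"),
                      curve = curves$TripleNegative, delay_days = 7),
    econ = econ
  )
  expect_gt(cf$delta$life_years, 0)
  expect_lt(cf$delta$death_prob, 0)
  expect_gt(cf$delta$migration_prob, 0)
  expect_error(counterfactual(scenario_a = list(stratum = NULL, cycles = 60),
                              scenario_b = list(stratum = NULL, cycles = 120)),
               "horizon")
})
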