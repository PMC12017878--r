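# Five-state monthly Markov cohort model.
#
# States: Symptomatic-Undiagnosed -> Diagnosed-Untreated ->
# Treatment-Initiated -> {Progressive-Disease -> Death, Death}; Death is
# absorbing. Only the published forward transitions are permitted; the
# diagonal is the complement of the listed exits. Membership is counted at
# cycle start (no half-cycle correction) and the annual 3.5% discount rate
# is compounded exactly per cycle as (1.035)^(-t/12).

MARKOV_STATES <- c("Symptomatic-Undiagnosed", "Diagnosed-Untreated",
                   "Treatment-Initiated", "Progressive-Disease", "Death")

# the permitted (from, to) exits of the model structure
MARKOV_EDGES <- rbind(
  c("Symptomatic-Undiagnosed", "Diagnosed-Untreated"),
  c("Diagnosed-Untreated", "Treatment-Initiated"),
  c("Treatment-Initiated", "Progressive-Disease"),
  c("Treatment-Initiated", "Death"),
  c("Progressive-Disease", "Death")
)

#' The five health states of the cohort model
#' @return character vector of state labels (Death last, absorbing).
#' @export
health_states <- function() MARKOV_STATES

#' Default monthly transition-probability table
#'
#' The published monthly transition probabilities, overall and stratified
#' (symptom type, time interval, stage, molecular subtype, treatment type,
#' stage at diagnosis), read from the package's plain-text parameter file.
#' Note that patients can die only from the Treatment-Initiated and
#' Progressive-Disease states: the source lists no death exit from the
#' pre-treatment states, a structural assumption carried as-is.
#'
#' @return data frame with columns `from`, `to`, `stratum_key`,
#'   `stratum_value`, `probability`.
#' @export
default_transition_table <- function() {
  read_transition_table(system.file("extdata", "transition_probabilities.csv",
                                    package = "oncodelay", mustWork = TRUE))
}

#' Read / write a transition table (delimited text)
#'
#' @param path CSV file with columns `from`, `to`, `stratum_key`,
#'   `stratum_value`, `probability`.
#' @param table a transition-table data frame.
#' @export
read_transition_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("from", "to", "stratum_key", "stratum_value", "probability")
  if (!all(needed %in% names(tab))) {
    stop("transition table needs columns: ", paste(needed, collapse = ", "))
  }
  if (any(tab$probability < 0 | tab$probability > 1)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  tab
}

#' @rdname read_transition_table
#' @export
write_transition_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Build the 5x5 monthly transition matrix for a stratum
#'
#' Off-diagonal entries come from the table, preferring rows matching the
#' requested stratum and falling back to the `Overall` row when no
#' stratified value is listed; the diagonal is 1 minus the row's exits and
#' the Death row is absorbing.
#'
#' @param table transition table, default [default_transition_table()].
#' @param stratum `NULL` for Overall, or a single named character value,
#'   e.g. `c("Molecular Subtype" = "TripleNegative")` or
#'   `c("Time Interval" = "2-6m")`.
#' @return row-stochastic 5x5 matrix with state dimnames.
#' @export
#' @examples
#' build_matrix()["Symptomatic-Undiagnosed", ]
build_matrix <- function(table = default_transition_table(), stratum = NULL) {
  if (!is.null(stratum) &&
      (length(stratum) != 1 || is.null(names(stratum)))) {
    stop("stratum must be NULL or a single named value")
  }
  m <- matrix(0, 5, 5, dimnames = list(MARKOV_STATES, MARKOV_STATES))
  for (e in seq_len(nrow(MARKOV_EDGES))) {
    from <- MARKOV_EDGES[e, 1]; to <- MARKOV_EDGES[e, 2]
    rows <- table[table$from == from & table$to == to, , drop = FALSE]
    hit <- NULL
    if (!is.null(stratum)) {
      hit <- rows[rows$stratum_key == names(stratum) &
                    rows$stratum_value == stratum[[1]], , drop = FALSE]
    }
    if (is.null(hit) || nrow(hit) == 0) {
      hit <- rows[rows$stratum_key == "Overall", , drop = FALSE]
    }
    if (nrow(hit) == 0) {
      stop(sprintf("no probability for %s -> %s (stratum or Overall)", from, to))
    }
    m[from, to] <- hit$probability[1]
  }
  exits <- rowSums(m)
  if (any(exits > 1 + 1e-12)) {
    bad <- MARKOV_STATES[which(exits > 1 + 1e-12)[1]]
    stop(sprintf("exit probabilities from state '%s' exceed 1 (stratum %s)",
                 bad, if (is.null(stratum)) "Overall" else stratum[[1]]))
  }
  diag(m) <- 1 - exits
  m["Death", ] <- c(0, 0, 0, 0, 1)
  m
}

#' Run a cohort trace
#'
#' Propagates an initial occupancy vector through a row-stochastic matrix:
#' `occupancy[t] = occupancy[t-1] %*% matrix`, for `cycles` monthly cycles.
#' Works for any square matrix (a `Death` column, when present, is checked
#' for monotonicity by the tests).
#'
#' @param matrix row-stochastic transition matrix.
#' @param initial_occupancy nonnegative vector summing to 1; default all
#'   mass in the first state.
#' @param cycles number of cycles (default 120, which captures >95% of
#'   outcomes at the published rates).
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   ((cycles+1) x k matrix, rows labelled 0..cycles) and `cycles`.
#' @export
run_trace <- function(matrix, initial_occupancy = NULL, cycles = 120L) {
  k <- nrow(matrix)
  if (is.null(initial_occupancy)) initial_occupancy <- c(1, rep(0, k - 1))
  if (cycles < 1) stop("cycles must be >= 1")
  if (length(initial_occupancy) != k || any(initial_occupancy < 0) ||
      abs(sum(initial_occupancy) - 1) > 1e-9) {
    stop("initial occupancy must be nonnegative and sum to 1")
  }
  occ <- matrix(NA_real_, cycles + 1, k,
                dimnames = list(0:cycles, colnames(matrix)))
  occ[1, ] <- initial_occupancy
  for (t in seq_len(cycles)) occ[t + 1, ] <- occ[t, ] %*% matrix
  structure(list(occupancy = occ, cycles = as.integer(cycles)),
            class = "cohort_trace")
}

#' Maximum-likelihood transition probabilities from event histories
#'
#' Estimates monthly probabilities as transition counts over person-months
#' at risk: `p(s -> s') = count(s -> s') / months observed in s`, per
#' stratum plus Overall. States with zero exposure yield no rows (missing,
#' not zero); [build_matrix()] then falls back to Overall.
#'
#' @param event_histories matrix (patients x months) of state labels, the
#'   per-patient monthly state sequences; or an object from [microsim()].
#' @param strata optional per-patient stratum labels; when given, per-
#'   stratum rows are emitted under `stratum_key`.
#' @param stratum_key label for the stratification variable.
#' @return transition-table data frame (off-diagonal transitions only).
#' @export
mle_transitions <- function(event_histories, strata = NULL,
                            stratum_key = "stratum") {
  if (inherits(event_histories, "markov_microsim")) {
    event_histories <- event_histories$paths
  }
  h <- as.matrix(event_histories)
  if (length(h) == 0 || ncol(h) < 2) {
    stop("event histories must contain at least two monthly observations")
  }
  estimate <- function(hh, key, value) {
    from <- as.vector(hh[, -ncol(hh)])
    to <- as.vector(hh[, -1])
    tab <- table(from, to)
    at_risk <- rowSums(tab)
    rows <- which(tab > 0, arr.ind = TRUE)
    out <- data.frame(
      from = rownames(tab)[rows[, 1]],
      to = colnames(tab)[rows[, 2]],
      stratum_key = key, stratum_value = value,
      probability = tab[rows] / at_risk[rows[, 1]],
      stringsAsFactors = FALSE
    )
    out[out$from != out$to, , drop = FALSE]
  }
  res <- estimate(h, "Overall", "Overall")
  if (!is.null(strata)) {
    for (s in sort(unique(strata))) {
      res <- rbind(res, estimate(h[strata == s, , drop = FALSE],
                                 stratum_key, s))
    }
  }
  rownames(res) <- NULL
  res
}

#' Economic parameters
#'
#' Cycle length 1 month, horizon 120 cycles (10 years), annual discount rate
#' 3.5%, published state utility weights (0.78, 0.70, 0.65, 0.45; Death 0)
#' and phase costs in SAR. The initial-treatment cost range
#' (15,300-42,800 SAR) is resolved by stage: linear from stage I (low) to
#' stage IV (high).
#'
#' @param discount_rate annual rate in \[0, 1).
#' @param horizon cycles.
#' @param utilities named utilities per alive state.
#' @param costs named phase costs (SAR).
#' @return list of class `economic_params`.
#' @export
economic_params <- function(discount_rate = 0.035, horizon = 120L,
                            utilities = c("Symptomatic-Undiagnosed" = 0.78,
                                          "Diagnosed-Untreated" = 0.70,
                                          "Treatment-Initiated" = 0.65,
                                          "Progressive-Disease" = 0.45,
                                          "Death" = 0),
                            costs = c(diagnostic = 2450,
                                      initial_treatment_low = 15300,
                                      initial_treatment_high = 42800,
                                      continuing_care = 4200,
                                      progressive_disease = 18700,
                                      terminal_care = 23500)) {
  if (discount_rate < 0 || discount_rate >= 1) {
    stop("discount rate must lie in [0, 1)")
  }
  if (!is.null(utilities[["Death"]]) && utilities[["Death"]] != 0) {
    stop("the Death utility is fixed at 0")
  }
  structure(list(cycle_length_months = 1, horizon = as.integer(horizon),
                 discount_rate = discount_rate, utilities = utilities,
                 costs = costs),
            class = "economic_params")
}

#' Per-cycle discount factor
#'
#' `(1 + rate)^(-t/12)` for cycle `t` in months: exact compounding of the
#' annual rate, so the factor at 12 months is `1/(1 + rate)`.
#'
#' @param t_months cycle time(s) in months.
#' @param rate annual discount rate.
#' @return numeric vector.
#' @export
discount_factor <- function(t_months, rate = 0.035) {
  (1 + rate)^(-t_months / 12)
}

# internal: stage-interpolated initial treatment cost
initial_treatment_cost <- function(costs, stage) {
  w <- (match(stage, STAGE_LABELS) - 1) / 3
  if (any(is.na(w))) stop("stage must be one of I, II, III, IV")
  costs[["initial_treatment_low"]] * (1 - w) +
    costs[["initial_treatment_high"]] * w
}

#' Accumulate discounted outcomes over a cohort trace
#'
#' Life-years and QALYs sum start-of-cycle occupancy over alive states,
#' 1/12 year per cycle, discounted at `(1.035)^(-t/12)`. Costs (computed
#' when the transition matrix is supplied) apply the diagnostic,
#' initial-treatment (stage-resolved), progressive-disease and terminal-care
#' amounts to state-entry flows and the continuing-care amount per month of
#' Treatment-Initiated occupancy.
#'
#' @param trace a [run_trace()] result.
#' @param econ an [economic_params()] object; its horizon must match the
#'   trace.
#' @param matrix transition matrix used to compute entry flows (optional;
#'   without it `discounted_cost` is `NA`).
#' @param stage stage used to resolve the initial-treatment cost range.
#' @return list with `life_years`, `qalys`, `discounted_cost`.
#' @export
accumulate <- function(trace, econ, matrix = NULL, stage = "II") {
  stopifnot(inherits(trace, "cohort_trace"), inherits(econ, "economic_params"))
  if (trace$cycles != econ$horizon) {
    stop(sprintf("horizon mismatch: trace has %d cycles, econ %d",
                 trace$cycles, econ$horizon))
  }
  occ <- trace$occupancy
  states <- colnames(occ)
  alive <- setdiff(states, "Death")
  u <- econ$utilities[states]
  if (any(is.na(u[alive]))) stop("utilities missing for some states")
  tt <- 0:(trace$cycles - 1)               # start-of-cycle membership
  d <- discount_factor(tt, econ$discount_rate)
  occ_cycle <- occ[seq_len(trace$cycles), , drop = FALSE]
  life_years <- sum((occ_cycle[, alive, drop = FALSE] %*% rep(1, length(alive))) * d) / 12
  qalys <- sum((occ_cycle %*% ifelse(is.na(u), 0, u)) * d) / 12
  cost <- NA_real_
  if (!is.null(matrix)) {
    cs <- econ$costs
    # entry flow into state s at cycle t: sum_{s' != s} occ[t-1, s'] P(s' -> s)
    off <- matrix; diag(off) <- 0
    entries <- occ_cycle %*% off              # rows: flows arriving at t+1
    dc <- discount_factor(tt + 1, econ$discount_rate)
    cost <- sum(entries[, "Diagnosed-Untreated"] * dc) * cs[["diagnostic"]] +
      sum(entries[, "Treatment-Initiated"] * dc) *
        initial_treatment_cost(cs, stage) +
      sum(entries[, "Progressive-Disease"] * dc) * cs[["progressive_disease"]] +
      sum(entries[, "Death"] * dc) * cs[["terminal_care"]] +
      sum(occ_cycle[, "Treatment-Initiated"] * d) * cs[["continuing_care"]]
    cost <- unname(cost)
  }
  list(life_years = unname(life_years), qalys = unname(qalys),
       discounted_cost = cost)
}

#' Counterfactual scenario comparison
#'
#' Builds the transition matrix for two scenarios that differ only in their
#' declared stratum (e.g. delay interval or molecular subtype), runs both
#' traces from the same initial occupancy, and reports outcome differences
#' (scenario A minus scenario B): life-years, QALYs, death probability at
#' horizon, and -- when a migration curve and delay are declared -- the
#' cumulative stage-migration probability.
#'
#' Note the model structure implies slower diagnosis *delays* exposure to
#' the treated-state mortality (no death exit is listed from the
#' pre-treatment states), so a slower-diagnosis stratum accrues more model
#' life-years at a fixed horizon even though its real-world survival is
#' worse; the survival consequences of delay enter through the hazard-ratio
#' gradient and stage migration, not through the diagnosis-speed stratum.
#'
#' @param table transition table.
#' @param scenario_a,scenario_b lists with elements `stratum` (named value
#'   or `NULL`), and optionally `curve` (a migration curve) and
#'   `delay_days`.
#' @param econ economic parameters (shared horizon; scenarios with a
#'   `cycles` element must agree).
#' @param initial_occupancy starting occupancy, default all symptomatic.
#' @return list of deltas: `life_years`, `qalys`, `death_prob`,
#'   `migration_prob` plus the per-scenario results.
#' @export
counterfactual <- function(table = default_transition_table(),
                           scenario_a, scenario_b,
                           econ = economic_params(),
                           initial_occupancy = NULL) {
  cyc_a <- scenario_a$cycles %||% econ$horizon
  cyc_b <- scenario_b$cycles %||% econ$horizon
  if (cyc_a != cyc_b) stop("scenarios must share the same horizon")
  eval_scenario <- function(sc) {
    m <- build_matrix(table, sc$stratum)
    tr <- run_trace(m, initial_occupancy, cyc_a)
    res <- accumulate(tr, econ, matrix = m, stage = sc$stage %||% "II")
    res$death_prob <- unname(tr$occupancy[cyc_a + 1, "Death"])
    res$migration_prob <- if (!is.null(sc$curve) && !is.null(sc$delay_days)) {
      migration_at(sc$curve, sc$delay_days)
    } else NA_real_
    res
  }
  a <- eval_scenario(scenario_a)
  b <- eval_scenario(scenario_b)
  list(delta = list(life_years = a$life_years - b$life_years,
                    qalys = a$qalys - b$qalys,
                    death_prob = a$death_prob - b$death_prob,
                    migration_prob = a$migration_prob - b$migration_prob),
       scenario_a = a, scenario_b = b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monte-Carlo microsimulation of the cohort model
#'
#' Simulates `n` independent patient paths through the transition matrix;
#' the occupancy estimates (with binomial standard errors) are the
#' stochastic oracle for [run_trace()], and the paths feed
#' [mle_transitions()] for parameter-recovery checks.
#'
#' @param matrix row-stochastic transition matrix with state dimnames.
#' @param n number of simulated patients.
#' @param cycles number of monthly cycles.
#' @param seed RNG seed.
#' @param initial_occupancy starting distribution, default all mass in the
#'   first state.
#' @return object of class `markov_microsim`: list with `paths`
#'   (n x (cycles+1) state-label matrix), `occupancy` ((cycles+1) x k
#'   estimates), `se` (binomial SEs), `n`.
#' @export
microsim <- function(matrix, n, cycles = 120L, seed = 1L,
                     initial_occupancy = NULL) {
  if (n < 1) stop("n must be >= 1")
  k <- nrow(matrix)
  states <- rownames(matrix)
  if (is.null(initial_occupancy)) initial_occupancy <- c(1, rep(0, k - 1))
  set.seed(seed)
  cur <- sample.int(k, n, replace = TRUE, prob = initial_occupancy)
  paths <- matrix(NA_integer_, n, cycles + 1)
  paths[, 1] <- cur
  for (t in seq_len(cycles)) {
    for (s in unique(cur)) {
      i <- which(cur == s)
      paths[i, t + 1] <- sample.int(k, length(i), replace = TRUE,
                                    prob = matrix[s, ])
    }
    cur <- paths[, t + 1]
  }
  occ <- t(apply(paths, 2, tabulate, nbins = k)) / n
  dimnames(occ) <- list(0:cycles, states)
  se <- sqrt(occ * (1 - occ) / n)
  label_paths <- matrix(states[paths], n, cycles + 1)
  structure(list(paths = label_paths, occupancy = occ, se = se, n = n),
            class = "markov_microsim")
}

#' Export a cohort trace as CSV
#'
#' @param trace a [run_trace()] result.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(cycle = 0:trace$cycles, trace$occupancy,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
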