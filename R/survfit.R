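# Kaplan-Meier and Cox proportional-hazards summaries, restricted-mean
# life-years lost, and model-calibration statistics. Product-limit and
# partial-likelihood estimation are delegated to the survival package
# (Breslow tie handling); step integration and the calibration statistics
# are implemented here.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with right censoring.
#'
#' @param times nonnegative follow-up times.
#' @param events 0/1 death indicators.
#' @return object of class `km_curve`: data frame with `time`, `n_risk`,
#'   `n_event`, `survival` (one row per observed time), with the maximum
#'   observed time stored as the `support` attribute.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("no observations")
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(times < 0)) stop("times must be nonnegative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    survival = sf$surv)
  attr(out, "support") <- max(times)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability of a KM curve at given times
#'
#' Right-continuous step-function evaluation; 1 before the first event.
#'
#' @param curve a [km_estimate()] object.
#' @param t times.
#' @return numeric vector.
#' @export
km_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  c(1, curve$survival)[idx + 1]
}

#' Restricted mean survival time of a KM curve
#'
#' Area under the step function from 0 to `horizon` (same time unit as the
#' curve).
#'
#' @param curve a [km_estimate()] object.
#' @param horizon upper integration limit; must not exceed the curve's
#'   observed support.
#' @return RMST in the curve's time unit.
#' @export
km_rmst <- function(curve, horizon) {
  if (horizon > attr(curve, "support") + 1e-9) {
    stop("horizon lies beyond the curve's observed support")
  }
  tt <- c(0, curve$time[curve$time < horizon], horizon)
  ss <- c(1, curve$survival[curve$time < horizon])
  sum(ss * diff(tt))
}

#' Life-years lost between two survival curves
#'
#' Difference in restricted mean survival time (reference minus exposed)
#' over a shared horizon, converted from months to years.
#'
#' @param curve_ref,curve_exposed [km_estimate()] objects on a monthly
#'   timescale.
#' @param horizon_months integration horizon (default 120, the model
#'   horizon).
#' @return years of life lost (nonnegative when the reference curve
#'   dominates).
#' @export
life_years_lost <- function(curve_ref, curve_exposed, horizon_months = 120) {
  (km_rmst(curve_ref, horizon_months) -
     km_rmst(curve_exposed, horizon_months)) / 12
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood (Breslow tie handling) for the given
#' covariates and returns hazard ratios with Wald confidence intervals.
#'
#' @param cohort data frame containing the time, event and covariate
#'   columns.
#' @param covariates character vector of covariate names (factors allowed).
#' @param time,event names of the follow-up time and event columns.
#' @param conf_level Wald CI level.
#' @return object of class `hazard_fit`: data frame with `term`, `coef`,
#'   `hr`, `se`, `hr_low`, `hr_high`, `z`, `p`; the fitted `coxph` object is
#'   attached as attribute `fit` and a logical `converged` flag records
#'   whether the fit converged cleanly.
#' @export
ph_fit <- function(cohort, covariates, time = "time_months", event = "event",
                   conf_level = 0.95) {
  if (sum(cohort[[event]]) < 1) stop("no events in the cohort")
  fml <- stats::as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                                  paste(covariates, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = cohort, ties = "breslow"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!converged) {
    stop("partial-likelihood fit failed to converge after ", fit$iter,
         " iterations")
  }
  co <- summary(fit)$coefficients
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(term = rownames(co), coef = co[, "coef"],
                    hr = exp(co[, "coef"]), se = co[, "se(coef)"],
                    hr_low = exp(co[, "coef"] - zq * co[, "se(coef)"]),
                    hr_high = exp(co[, "coef"] + zq * co[, "se(coef)"]),
                    z = co[, "z"], p = co[, "Pr(>|z|)"],
                    row.names = NULL)
  attr(out, "fit") <- fit
  attr(out, "converged") <- converged
  class(out) <- c("hazard_fit", "data.frame")
  out
}

#' Model-calibration and prediction-error statistics
#'
#' Hosmer-Lemeshow calibration over equal-count risk deciles (chi-square
#' with `bins - 2` degrees of freedom), the concordance statistic over
#' comparable pairs, mean absolute percentage error over nonzero observed
#' values, and root mean square error. These are the validation statistics
#' of the model-specification table; reproducing their published values
#' requires the original patient data, so only the formulas (and their
#' null-distribution properties) are checked here.
#'
#' @param predicted_probs predicted event probabilities in \[0, 1\].
#' @param observed_events 0/1 outcomes aligned with `predicted_probs`.
#' @param predicted_values,observed_values aligned numeric vectors for
#'   MAPE/RMSE.
#' @param bins number of Hosmer-Lemeshow bins (default 10).
#' @return list of class `validation_stats`: `hosmer_lemeshow` (statistic,
#'   df, p_value), `c_statistic`, `mape` (percent), `rmse`.
#' @export
validation_stats <- function(predicted_probs, observed_events,
                             predicted_values, observed_values, bins = 10L) {
  if (length(predicted_probs) != length(observed_events) ||
      length(predicted_values) != length(observed_values)) {
    stop("inputs must be aligned vectors")
  }
  if (any(predicted_probs < 0 | predicted_probs > 1)) {
    stop("predicted probabilities must lie in [0, 1]")
  }
  # Hosmer-Lemeshow over equal-count deciles of predicted risk
  br <- unique(stats::quantile(predicted_probs, probs = seq(0, 1, length.out = bins + 1)))
  grp <- if (length(br) < 3) factor(rep(1, length(predicted_probs))) else
    cut(predicted_probs, breaks = br, include.lowest = TRUE)
  obs <- tapply(observed_events, grp, sum)
  exp_ <- tapply(predicted_probs, grp, sum)
  n_g <- tapply(predicted_probs, grp, length)
  keep <- !is.na(obs)
  obs <- obs[keep]; exp_ <- exp_[keep]; n_g <- n_g[keep]
  denom <- exp_ * (1 - exp_ / n_g)
  ok <- denom > 0
  hl_stat <- sum((obs[ok] - exp_[ok])^2 / denom[ok])
  hl_df <- max(length(obs) - 2, 1)
  hl_p <- stats::pchisq(hl_stat, df = hl_df, lower.tail = FALSE)
  # concordance (Mann-Whitney form)
  n1 <- sum(observed_events == 1); n0 <- sum(observed_events == 0)
  cstat <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(predicted_probs)
    (sum(r[observed_events == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  nz <- observed_values != 0
  if (!any(nz)) stop("MAPE undefined: all observed values are zero")
  mape <- mean(abs(predicted_values[nz] - observed_values[nz]) /
                 abs(observed_values[nz])) * 100
  rmse <- sqrt(mean((predicted_values - observed_values)^2))
  structure(list(hosmer_lemeshow = list(statistic = unname(hl_stat),
                                        df = hl_df, p_value = unname(hl_p)),
                 c_statistic = unname(cstat), mape = mape, rmse = rmse),
            class = "validation_stats")
}

#' Export a KM curve as CSV
#'
#' @param curve a [km_estimate()] object.
#' @param path file path.
#' @export
write_km <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
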