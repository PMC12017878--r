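# Delay taxonomy and reference constants shared across the package.
# Conventions: 1 month = 30 days, 1 year = 365 days; category day ranges are
# half-open [lower, upper); the open-ended >=1y band is truncated at 730 days.

DELAY_LABELS <- c("<2w", "2w-1m", "1-2m", "2-6m", "6-12m", ">=1y")
HIGH_RISK_LABELS <- c("2-6m", "6-12m", ">=1y")
SUBTYPE_LABELS <- c("HR+", "HER2+", "TripleNegative")
STAGE_LABELS <- c("I", "II", "III", "IV")
AGE_BAND_LABELS <- c("<40", "40-60", ">60")

#' Diagnostic delay categories
#'
#' The six clinically defined delay bands used throughout the package, with
#' their day ranges (half-open, `[lower_day, upper_day)`) and the fixed
#' representative day at which stage-migration curves are evaluated for each
#' band. Representative days are anchor-aligned month ends
#' (0, 30, 60, 180, 270, 360), chosen so the combined delay-assessment grid
#' lands exactly on the published 1/3/6/12-month anchor probabilities; for
#' several bands this evaluation day lies on or outside the band's own day
#' range by construction.
#'
#' @return A data frame with one row per category: `label`, `lower_day`,
#'   `upper_day`, `representative_day`, `high_risk` (delay over two months).
#' @export
#' @examples
#' delay_categories()
delay_categories <- function() {
  data.frame(
    label = DELAY_LABELS,
    lower_day = c(0L, 14L, 30L, 60L, 180L, 365L),
    upper_day = c(14L, 30L, 60L, 180L, 365L, 730L),
    representative_day = c(0L, 30L, 60L, 180L, 270L, 360L),
    high_risk = DELAY_LABELS %in% HIGH_RISK_LABELS,
    stringsAsFactors = FALSE
  )
}

#' Observed delay-category distribution
#'
#' Patient counts per delay category among the 639 symptomatic patients of
#' the source cohort (45, 84, 40, 241, 60, 169).
#'
#' @return A list with `counts` (named integer vector) and `denominator`.
#' @export
delay_distribution <- function() {
  counts <- c(45L, 84L, 40L, 241L, 60L, 169L)
  names(counts) <- DELAY_LABELS
  list(counts = counts, denominator = 639L)
}

#' Published per-category outcome constants
#'
#' Reference constants reported per delay category: mortality hazard ratios
#' with 95% CIs, life-years lost (LYL), QALY loss, and the odds ratio for
#' requiring more intensive treatment. The LYL and QALY-loss columns are
#' carried verbatim as reference constants (their derivation is not stated in
#' the source and is not reproducible from the printed hazard ratios over the
#' 10-year model horizon); the hazard ratios and treatment-intensity odds are
#' also the generating values used by [generate_cohort()].
#'
#' @return A data frame with one row per delay category.
#' @export
delay_reference_table <- function() {
  data.frame(
    label = DELAY_LABELS,
    count = c(45L, 84L, 40L, 241L, 60L, 169L),
    hr = c(1, 1.18, 1.27, 1.54, 1.92, 2.35),
    hr_low = c(NA, 1.05, 1.13, 1.37, 1.68, 2.06),
    hr_high = c(NA, 1.32, 1.42, 1.73, 2.19, 2.67),
    lyl_years = c(0, 0.7, 1.2, 2.8, 4.3, 6.7),
    qaly_loss = c(0, 0.8, 1.4, 3.2, 4.9, 7.6),
    intensity_or = c(1, 1.3, 1.7, 2.4, 3.1, 3.8),
    stringsAsFactors = FALSE
  )
}

#' Map a delay in days to its category
#'
#' @param delay_days integer vector of delays in days (0 to 729).
#' @return character vector of category labels.
#' @export
delay_category_of <- function(delay_days) {
  if (any(delay_days < 0)) stop("delay_days must be nonnegative")
  cats <- delay_categories()
  idx <- findInterval(delay_days, cats$lower_day)
  idx[delay_days >= 730] <- 6L
  cats$label[idx]
}

# internal: validate a probability vector
check_probs <- function(p, what, tol = 1e-12) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop(sprintf("%s must be finite and nonnegative", what))
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("%s must sum to 1 (got %.15f)", what, sum(p)))
  }
  invisible(p)
}
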