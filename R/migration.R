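# Cumulative stage-migration curves, critical-delay thresholds and NNT.
#
# A curve is anchored at (0, 0) and at the published 1/3/6/12-month
# cumulative migration probabilities; between anchors the default scheme is
# piecewise-linear interpolation in days (1 month = 30 days), constant beyond
# the last anchor. A geometric per-month alternative, p(d) = 1 - (1 - p1)^(d/30)
# with p1 the 1-month anchor, is available behind the `scheme` argument.

#' Build a cumulative stage-migration curve
#'
#' @param group label of the group the curve describes (a stage transition,
#'   molecular class, or age band).
#' @param anchors a data frame or 2-column matrix with columns `month`
#'   (strictly increasing, positive) and `probability` (nondecreasing, in
#'   \[0, 1\]). The origin anchor (0, 0) is prepended when absent. An empty
#'   set of anchors yields a curve that is identically zero.
#' @return An object of class `migration_curve`.
#' @export
#' @examples
#' tn <- build_curve("TripleNegative",
#'                   data.frame(month = c(1, 3, 6, 12),
#'                              probability = c(0.053, 0.159, 0.318, 0.536)))
#' migration_at(tn, 90)
build_curve <- function(group, anchors) {
  anchors <- as.data.frame(anchors)
  if (nrow(anchors) == 0) {
    anchors <- data.frame(month = numeric(0), probability = numeric(0))
  }
  names(anchors)[1:2] <- c("month", "probability")
  if (nrow(anchors) > 0) {
    if (any(anchors$probability < 0 | anchors$probability > 1)) {
      stop("anchor probabilities must lie in [0, 1]")
    }
    if (any(duplicated(anchors$month)) || is.unsorted(anchors$month, strictly = TRUE)) {
      stop("anchor times must be strictly increasing with no duplicates")
    }
    if (is.unsorted(anchors$probability)) {
      stop(sprintf("anchor probabilities must be nondecreasing for group '%s'", group))
    }
  }
  if (nrow(anchors) == 0 || anchors$month[1] > 0) {
    anchors <- rbind(data.frame(month = 0, probability = 0), anchors)
  }
  if (anchors$probability[1] != 0) stop("curve must start at probability 0")
  rownames(anchors) <- NULL
  structure(list(group = group, anchors = anchors), class = "migration_curve")
}

#' @export
print.migration_curve <- function(x, ...) {
  cat("Stage-migration curve:", x$group, "\n")
  print(x$anchors, row.names = FALSE)
  invisible(x)
}

#' Cumulative migration probability at a given delay
#'
#' @param curve a [build_curve()] object.
#' @param delay_days nonnegative delay(s) in days.
#' @param scheme `"linear"` (default): piecewise-linear between anchors,
#'   constant beyond the last; `"geometric"`: constant per-month migration
#'   hazard implied by the 1-month anchor.
#' @return numeric vector of probabilities.
#' @export
migration_at <- function(curve, delay_days, scheme = c("linear", "geometric")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(curve, "migration_curve"))
  if (any(delay_days < 0)) stop("delay_days must be nonnegative")
  a <- curve$anchors
  if (scheme == "geometric") {
    nz <- which(a$probability > 0)
    if (length(nz) == 0) return(rep(0, length(delay_days)))
    p1 <- a$probability[nz[1]]
    m1 <- a$month[nz[1]]
    return(1 - (1 - p1)^(delay_days / (30 * m1)))
  }
  if (nrow(a) == 1) return(rep(0, length(delay_days)))
  stats::approx(a$month * 30, a$probability, xout = delay_days, rule = 2)$y
}

#' Critical delay threshold of a migration curve
#'
#' The smallest integer day at which the cumulative stage-migration
#' probability reaches a given level (default 10%), found by a day-by-day
#' scan; "exceeds" is read as `>=` at integer days. Returns `NA` when the
#' curve never reaches the level.
#'
#' @inheritParams migration_at
#' @param level probability level in (0, 1); default 0.10.
#' @param arr optional absolute risk reduction used to attach an NNT
#'   (`ceiling(1/arr)`) to the result.
#' @return A list of class `threshold_result` with `group`, `threshold_days`
#'   (integer or `NA`), `level`, `scheme` and `nnt` (integer or `NA`).
#' @export
critical_threshold <- function(curve, level = 0.10,
                               scheme = c("linear", "geometric"), arr = NULL) {
  scheme <- match.arg(scheme)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must be a single probability in (0, 1)")
  }
  max_day <- if (scheme == "linear") max(curve$anchors$month) * 30 else 3650
  days <- 0:max_day
  p <- migration_at(curve, days, scheme = scheme)
  hit <- which(p >= level)
  threshold <- if (length(hit)) days[hit[1]] else NA_integer_
  structure(list(group = curve$group,
                 threshold_days = threshold,
                 level = level,
                 scheme = scheme,
                 nnt = if (is.null(arr)) NA_integer_ else nnt(arr)),
            class = "threshold_result")
}

#' Number needed to treat
#'
#' `ceiling(1 / arr)`: the number of patients who must receive an expedited
#' diagnostic pathway to prevent one stage migration, given the absolute risk
#' reduction `arr`.
#'
#' @param absolute_risk_reduction risk difference in (0, 1].
#' @return integer NNT.
#' @export
#' @examples
#' nnt(0.117) # 9
nnt <- function(absolute_risk_reduction) {
  if (any(!is.finite(absolute_risk_reduction)) ||
      any(absolute_risk_reduction <= 0) || any(absolute_risk_reduction > 1)) {
    stop("absolute risk reduction must lie in (0, 1]")
  }
  as.integer(ceiling(1 / absolute_risk_reduction))
}

#' Default migration curves from the published anchors
#'
#' Curves for the three single-step stage transitions and the three
#' molecular classes, anchored at the published 1/3/6/12-month cumulative
#' migration probabilities.
#'
#' @return Named list of [build_curve()] objects.
#' @export
default_migration_curves <- function() {
  anchors <- list(
    "StageI-II"      = c(0.038, 0.117, 0.245, 0.429),
    "StageII-III"    = c(0.027, 0.082, 0.178, 0.336),
    "StageIII-IV"    = c(0.019, 0.058, 0.121, 0.243),
    "HR+"            = c(0.021, 0.065, 0.137, 0.258),
    "TripleNegative" = c(0.053, 0.159, 0.318, 0.536),
    "HER2+"          = c(0.038, 0.114, 0.228, 0.427)
  )
  months <- c(1, 3, 6, 12)
  out <- lapply(names(anchors), function(g) {
    build_curve(g, data.frame(month = months, probability = anchors[[g]]))
  })
  names(out) <- names(anchors)
  out
}

#' Published critical thresholds and NNTs (reference constants)
#'
#' The critical-delay thresholds (days to 10% cumulative migration risk) and
#' NNTs as printed in the source tables. These are carried as labelled
#' reference constants: they are not derivable from the printed curve anchors
#' under either interpolation scheme (the combined-assessment table also
#' prints a second, different set of stage-transition thresholds, included
#' here under `source = "combined table"`). Use [threshold_report()] to see
#' the thresholds this package computes from the anchors alongside these.
#'
#' @return data frame with `group`, `threshold_days`, `nnt`, `source`.
#' @export
reference_thresholds <- function() {
  data.frame(
    group = c("TripleNegative", "HER2+", "HR+",
              "StageI-II", "StageII-III", "StageIII-IV",
              "Age<40", "Age40-60", "Age>60",
              "StageI-II", "StageII-III", "StageIII-IV"),
    threshold_days = c(38L, 52L, 85L, 56L, 68L, 73L, 48L, 65L, 92L, 78L, 92L, 115L),
    nnt = c(6L, 10L, 16L, 9L, 13L, 14L, 8L, 12L, 17L, NA, NA, NA),
    source = c(rep("subgroup table", 9), rep("combined table", 3)),
    stringsAsFactors = FALSE
  )
}

#' Computed thresholds alongside the published reference constants
#'
#' For each curve, the critical threshold computed by day-scan under the
#' linear and geometric schemes, a computed NNT (`ceiling(1/p)` at the
#' 3-month anchor, the rule consistent with most published NNTs), and the
#' published threshold/NNT where one exists.
#'
#' @param curves named list of curves, default [default_migration_curves()].
#' @param level threshold level, default 0.10.
#' @return data frame, one row per curve.
#' @export
threshold_report <- function(curves = default_migration_curves(), level = 0.10) {
  refs <- reference_thresholds()
  refs <- refs[refs$source == "subgroup table", ]
  rows <- lapply(curves, function(cv) {
    p3 <- migration_at(cv, 90)
    i <- match(cv$group, refs$group)
    data.frame(
      group = cv$group,
      threshold_linear_days = critical_threshold(cv, level, "linear")$threshold_days,
      threshold_geometric_days = critical_threshold(cv, level, "geometric")$threshold_days,
      nnt_computed = if (p3 > 0) nnt(p3) else NA_integer_,
      threshold_printed_days = if (is.na(i)) NA_integer_ else refs$threshold_days[i],
      nnt_printed = if (is.na(i)) NA_integer_ else refs$nnt[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read migration curves from a delimited parameter file
#'
#' @param path CSV with columns `group`, `month`, `probability`; defaults to
#'   the package's copy of the published anchors.
#' @return named list of [build_curve()] objects.
#' @export
read_migration_curves <- function(path = system.file("extdata",
                                                     "migration_anchors.csv",
                                                     package = "oncodelay",
                                                     mustWork = TRUE)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "month", "probability") %in% names(tab))) {
    stop("curve file needs columns group, month, probability")
  }
  groups <- unique(tab$group)
  out <- lapply(groups, function(g) {
    build_curve(g, tab[tab$group == g, c("month", "probability")])
  })
  names(out) <- groups
  out
}

#' Migration probabilities by delay category
#'
#' Evaluates each curve at each delay category's representative day
#' (0, 30, 60, 180, 270, 360); the reference category (`<2w`) is defined as 0.
#'
#' @param curves named list of [build_curve()] objects.
#' @param categories data frame as returned by [delay_categories()].
#' @return data frame: one row per curve group, one column per category.
#' @export
#' @examples
#' migration_grid()[, c("group", ">=1y")]
migration_grid <- function(curves = default_migration_curves(),
                           categories = delay_categories()) {
  if (length(curves) == 0) stop("no curves supplied")
  if (any(vapply(curves, function(cv) !inherits(cv, "migration_curve"), TRUE))) {
    stop("all elements of curves must be migration_curve objects")
  }
  grid <- vapply(curves, function(cv) {
    migration_at(cv, categories$representative_day)
  }, numeric(nrow(categories)))
  out <- as.data.frame(t(grid))
  names(out) <- categories$label
  out[["<2w"]] <- 0  # reference category, by definition
  cbind(data.frame(group = names(curves), stringsAsFactors = FALSE), out,
        row.names = NULL)
}
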