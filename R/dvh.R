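# Dose-volume histogram metrics and plan comparison.

#' Dose at volume (Dx%)
#'
#' `Dx%` is the largest dose `d` such that at least `x%` of the structure's
#' volume receives `>= d` — the inverse cumulative DVH, with linear
#' interpolation between voxel-dose order statistics (the left-continuous
#' type-4 quantile of the voxel doses at probability `1 - x/100`, which
#' reduces to the exact sort-and-count answer at the order statistics).
#'
#' @param p A [PlanResult-class].
#' @param structure Canonical role (e.g. `"BRAIN_CTV"`).
#' @param x Volume percentage, `0 < x < 100`.
#' @return Dose in Gy.
#' @export
doseAtVolume <- function(p, structure, x) {
  stopifnot(is(p, "PlanResult"))
  if (x <= 0 || x >= 100) stop("x must be strictly between 0 and 100")
  d <- structureDose(p, structure)
  if (length(d) == 0) stop("empty structure mask for ", structure)
  stats::quantile(d, probs = 1 - x / 100, names = FALSE, type = 4)
}

#' Mean structure dose
#'
#' Volume-weighted mean voxel dose (voxels are equal-volume, so the plain
#' average).
#'
#' @inheritParams doseAtVolume
#' @return Mean dose in Gy.
#' @export
meanDose <- function(p, structure) {
  stopifnot(is(p, "PlanResult"))
  d <- structureDose(p, structure)
  if (length(d) == 0) stop("empty structure mask for ", structure)
  mean(d)
}

#' The evaluation metric set of a plan
#'
#' D1%, D95% and D99% for the CTV; mean dose for each eye and lens.
#'
#' @param p A [PlanResult-class].
#' @return Named numeric vector: `D1_BRAIN_CTV`, `D95_BRAIN_CTV`,
#'   `D99_BRAIN_CTV`, `Mean_EYE_L`, `Mean_EYE_R`, `Mean_LENS_L`,
#'   `Mean_LENS_R` (Gy).
#' @export
dvhMetrics <- function(p) {
  stopifnot(is(p, "PlanResult"))
  out <- c(
    D1_BRAIN_CTV = doseAtVolume(p, "BRAIN_CTV", 1),
    D95_BRAIN_CTV = doseAtVolume(p, "BRAIN_CTV", 95),
    D99_BRAIN_CTV = doseAtVolume(p, "BRAIN_CTV", 99),
    Mean_EYE_L = meanDose(p, "EYE_L"),
    Mean_EYE_R = meanDose(p, "EYE_R"),
    Mean_LENS_L = meanDose(p, "LENS_L"),
    Mean_LENS_R = meanDose(p, "LENS_R")
  )
  out
}

#' Rescale a plan to a reference CTV D95%
#'
#' Multiplies every voxel dose by `referenceD95 / currentD95`, so the
#' resulting CTV D95% equals the reference exactly (all other Dx% scale by
#' the same factor; the operation is idempotent).
#'
#' @param p A [PlanResult-class] with positive CTV D95%.
#' @param referenceD95 Target CTV D95% in Gy.
#' @return The rescaled [PlanResult-class].
#' @export
normalizeToD95 <- function(p, referenceD95) {
  stopifnot(is(p, "PlanResult"))
  cur <- doseAtVolume(p, "BRAIN_CTV", 95)
  if (cur <= 0) stop("cannot normalize: current D95% is zero")
  scale <- referenceD95 / cur
  p@structureDose <- lapply(p@structureDose, function(d) d * scale)
  p
}

#' Paired dosimetric comparison of two plan cohorts
#'
#' Per-metric means, standard deviations, and paired two-sided t-tests at
#' the 0.05 level. Zero-variance paired differences are reported as
#' `p = 1` with a degenerate-case flag instead of NaN.
#'
#' @param aMetrics,bMetrics Equal-length lists (>= 2) of [dvhMetrics()]
#'   vectors, paired case by case.
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame with one row per metric: means +- sd of both cohorts,
#'   mean difference, t statistic, p value, `significant` and `degenerate`
#'   flags.
#' @export
comparePlans <- function(aMetrics, bMetrics, alpha = 0.05) {
  if (length(aMetrics) != length(bMetrics)) stop("paired lists differ in length")
  if (length(aMetrics) < 2) stop("need at least 2 paired cases")
  A <- do.call(rbind, aMetrics)
  B <- do.call(rbind, bMetrics)
  if (!identical(colnames(A), colnames(B))) stop("metric sets differ between cohorts")
  rows <- lapply(colnames(A), function(metric) {
    a <- A[, metric]
    b <- B[, metric]
    dif <- a - b
    degenerate <- stats::sd(dif) < 1e-12
    if (degenerate) {
      tStat <- 0
      pVal <- 1
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      tStat <- unname(tt$statistic)
      pVal <- tt$p.value
    }
    data.frame(
      metric = metric,
      mean_a = mean(a), sd_a = stats::sd(a),
      mean_b = mean(b), sd_b = stats::sd(b),
      mean_diff = mean(dif),
      t = tStat, p = pVal,
      significant = !degenerate && pVal < alpha,
      degenerate = degenerate
    )
  })
  do.call(rbind, rows)
}
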