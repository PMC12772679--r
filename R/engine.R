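# Surrogate Auto-FiF plan engine.
#
# A synthetic stand-in for a commercial TPS's Auto-FiF function, exposed
# behind the TpsAdapter interface so a real engine can be substituted
# without touching any other module. It is NOT a dose calculation; it is a
# parametric dose model engineered to reproduce the qualitative behaviour of
# field-in-field WBRT planning:
#   (a) two lateral opposed fields with a seeded heterogeneity pattern
#       creating interior hotspots;
#   (b) each subfield compresses the hottest dose region, so CTV D1% is
#       non-increasing in the number of subfields;
#   (c) raising target coverage priority lifts the peripheral (cold) CTV
#       dose strongly (~6-8% D95 per 25-point step) while scatter to the
#       eyes/lenses rises slowly (~1.6% per step) - the coverage/sparing
#       trade-off;
#   (d) larger (min MU, min area) settings coarsen the achievable
#       homogeneity: the subfield compression retains a larger fraction of
#       the excess above threshold, so CTV D1% - D99% is non-increasing in
#       fineness (non-decreasing in the combo index).
# All outputs are tagged "surrogate-fif".

.MU_LEVELS <- c(2, 4, 6, 8)
.AREA_LEVELS <- c(4, 6, 9, 10)

# Fineness/coarseness strength of a (mu, area) setting: a bijection of the
# 4 x 4 crossing onto 0..15, increasing in both mu and area, and increasing
# along the four clinical combos (2,4) < (4,6) < (6,9) < (8,10).
muAreaStrength <- function(mu, area) {
  mi <- match(mu, .MU_LEVELS)
  ai <- match(area, .AREA_LEVELS)
  if (is.na(mi) || is.na(ai)) stop("invalid (mu, area) setting: ", mu, ", ", area)
  (mi - 1) + 4 * (ai - 1)
}

#' TpsAdapter: pluggable plan-engine interface
#'
#' Any planning backend is represented by a `generatePlan(s, h, prescription,
#' seed)` function returning a [PlanResult-class]. Optional `newContext` /
#' `planFromContext` members let grid searches reuse per-case precomputation.
#'
#' @param name Engine tag recorded in every plan.
#' @param generatePlan Function `(s, h, prescription, seed) -> PlanResult`.
#' @param newContext Optional function `(s, seed) -> context`.
#' @param planFromContext Optional function `(context, h, prescription) ->
#'   PlanResult`.
#' @return A `TpsAdapter` (classed list).
#' @export
tpsAdapter <- function(name, generatePlan, newContext = NULL, planFromContext = NULL) {
  stopifnot(is.function(generatePlan))
  structure(
    list(
      name = name, generatePlan = generatePlan,
      newContext = newContext, planFromContext = planFromContext
    ),
    class = "TpsAdapter"
  )
}

#' @export
print.TpsAdapter <- function(x, ...) {
  cat(
    "TpsAdapter:", x$name,
    if (!is.null(x$newContext)) "(context-capable)" else "", "\n"
  )
  invisible(x)
}

# Precompute the geometry-dependent fields of the surrogate dose model for
# one case: structure masks, CTV boundary depth, the seeded hotspot field and
# OAR distance attenuation. Hyperparameter-independent, so a grid search
# pays this once.
surrogatePlanContext <- function(s, seed = 1, spacing = 2) {
  stopifnot(is(s, "StructureSet"))
  validObject(s)
  masks <- lapply(s@structures, voxelizeStructure, spacing = spacing)
  brainPts <- s@structures[["BRAIN_CTV"]]
  slices <- cloudSlices(brainPts)
  sliceZ <- vapply(slices, function(sl) sl$z, numeric(1))

  bm <- masks[["BRAIN_CTV"]]
  depth <- numeric(nrow(bm))
  for (zc in unique(bm[, 3])) {
    idx <- which(bm[, 3] == zc)
    sl <- slices[[which.min(abs(sliceZ - zc))]]
    ring <- sl$points
    d2 <- outer(bm[idx, 1], ring[, 1], "-")^2 + outer(bm[idx, 2], ring[, 2], "-")^2
    depth[idx] <- sqrt(apply(d2, 1, min))
  }
  w <- exp(-depth / 15) # boundary weight: 1 at surface, ->0 deep (mm scale 15)

  # seeded hotspot pattern: a few Gaussian bumps deep in the CTV
  deepIdx <- which(depth > 20)
  if (length(deepIdx) == 0) deepIdx <- which(depth >= stats::quantile(depth, 0.9))
  g <- withSeed(seed, {
    nBumps <- 3L
    centers <- bm[sample(deepIdx, nBumps, replace = length(deepIdx) < nBumps), , drop = FALSE]
    amps <- stats::runif(nBumps, 0.10, 0.18)
    sigmas <- stats::runif(nBumps, 12, 22)
    acc <- numeric(nrow(bm))
    for (k in seq_len(nBumps)) {
      d2 <- (bm[, 1] - centers[k, 1])^2 + (bm[, 2] - centers[k, 2])^2 +
        (bm[, 3] - centers[k, 3])^2
      acc <- acc + amps[k] * exp(-d2 / (2 * sigmas[k]^2))
    }
    acc
  })

  # OAR attenuation: exp(-gap/80mm) of the 3D distance to the CTV surface
  ref <- brainPts
  if (nrow(ref) > 900) ref <- ref[seq(1, nrow(ref), length.out = 900), ]
  oarFactor <- lapply(.oarRoles(), function(role) {
    om <- masks[[role]]
    d2 <- outer(rowSums(om^2), rowSums(ref^2), "+") - 2 * tcrossprod(om, ref)
    exp(-sqrt(pmax(apply(d2, 1, min), 0)) / 80)
  })
  names(oarFactor) <- .oarRoles()

  list(
    caseId = s@caseId, seed = seed, spacing = spacing,
    voxelVolume = (spacing / 10)^3,
    w = w, g = g, oarFactor = oarFactor
  )
}

# Evaluate the surrogate dose model for one hyperparameter setting.
surrogatePlanFromContext <- function(ctx, h, prescription = 30) {
  stopifnot(is(h, "AutoFifHyperparameters"))
  validObject(h)
  if (prescription <= 0) stop("prescription must be positive")
  P <- prescription
  f <- h@coveragePriority / 100
  n <- h@nSubfields
  s <- muAreaStrength(h@minSegmentMU, h@minSegmentArea)

  base <- P * (1.06 - 0.30 * ctx$w + 0.28 * f * ctx$w + ctx$g)
  # subfield passes: compress the excess above descending base quantiles;
  # coarser (mu, area) settings retain a larger fraction beta of the excess
  beta <- 0.25 + 0.045 * s
  thresholds <- stats::quantile(base, c(0.97, 0.93, 0.89), names = FALSE, type = 7)
  brain <- base
  for (k in seq_len(n)) {
    t <- thresholds[k]
    hot <- brain > t
    brain[hot] <- t + (brain[hot] - t) * beta
  }

  oarScale <- (0.60 + 0.04 * f) * (1 - 0.06 * (n - 1))
  doses <- c(
    list(BRAIN_CTV = brain),
    lapply(ctx$oarFactor, function(fac) P * fac * oarScale)
  )
  new("PlanResult",
    structureDose = doses, voxelVolume = ctx$voxelVolume,
    spacing = ctx$spacing, hyperparameters = h, prescription = P,
    seed = ctx$seed, engine = "surrogate-fif"
  )
}

#' The surrogate plan engine
#'
#' Builds a [tpsAdapter()] around the synthetic dose model (see the package
#' vignette for the model and the behavioural contracts it guarantees).
#'
#' @param spacing Dose-grid voxel spacing in mm (default 2, isotropic).
#' @return A `TpsAdapter`.
#' @export
surrogateEngine <- function(spacing = 2) {
  tpsAdapter(
    name = "surrogate-fif",
    generatePlan = function(s, h, prescription = 30, seed = 1) {
      ctx <- surrogatePlanContext(s, seed = seed, spacing = spacing)
      surrogatePlanFromContext(ctx, h, prescription)
    },
    newContext = function(s, seed = 1) surrogatePlanContext(s, seed = seed, spacing = spacing),
    planFromContext = surrogatePlanFromContext
  )
}

#' Generate one surrogate Auto-FiF plan
#'
#' Convenience wrapper over [surrogateEngine()]: deterministic for a fixed
#' `(s, h, seed)` triple.
#'
#' @param s A [StructureSet-class].
#' @param h An [AutoFifHyperparameters-class].
#' @param prescription Prescription dose in Gy (default 30).
#' @param seed Integer seed fixing the heterogeneity pattern.
#' @param spacing Voxel spacing (mm).
#' @return A [PlanResult-class].
#' @export
generatePlan <- function(s, h, prescription = 30, seed = 1, spacing = 2) {
  surrogateEngine(spacing)$generatePlan(s, h, prescription, seed)
}
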