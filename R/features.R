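#' Canonical geometric feature registry
#'
#' The 21 raw features computed from a structure set, after lateral-symmetry
#' averaging: volume, surface area and diameter of brain, eye and lens
#' (9); inter-organ centroid distances (3); isocenter-to-centroid distances
#' (3); polar and azimuthal angles from the isocenter to each organ centroid
#' (6). Units: cm, cm^2, cm^3 and radians, regardless of the millimetre
#' input — one unit system end to end.
#'
#' @return Character vector of the 21 canonical names, in registry order.
#' @export
featureRegistry <- function() {
  c(
    "Volume_Brain", "Volume_Eye", "Volume_Lens",
    "SurfaceArea_Brain", "SurfaceArea_Eye", "SurfaceArea_Lens",
    "Diameter_Brain", "Diameter_Eye", "Diameter_Lens",
    "Brain_Eye", "Brain_Lens", "Eye_Lens",
    "Brain_Iso", "Eye_Iso", "Lens_Iso",
    "Brain_Iso_Pol", "Eye_Iso_Pol", "Lens_Iso_Pol",
    "Brain_Iso_Azm", "Eye_Iso_Azm", "Lens_Iso_Azm"
  )
}

#' The shipped selected feature subset
#'
#' The 10-feature subset used by the classifier heads: the three organ
#' diameters, the three isocenter distances, and the eye/lens polar and
#' azimuthal angles.
#'
#' @return Character vector of 10 canonical names.
#' @export
selectedFeatureNames <- function() {
  c(
    "Diameter_Brain", "Diameter_Eye", "Diameter_Lens",
    "Brain_Iso", "Eye_Iso", "Lens_Iso",
    "Eye_Iso_Pol", "Lens_Iso_Pol", "Eye_Iso_Azm", "Lens_Iso_Azm"
  )
}

#' Extract the 21 geometric features of a case
#'
#' Computes per-organ size descriptors and isocenter-relative position
#' descriptors, then averages laterally paired quantities (left/right eyes
#' and lenses) arithmetically. The eye-lens distance pairs the same-side eye
#' with the same-side lens before averaging.
#'
#' @param s A [StructureSet-class].
#' @param spacing Slice width (mm) passed to the volume/area integrators.
#' @return Named numeric vector of length 21 (see [featureRegistry()]).
#' @export
extractFeatures <- function(s, spacing = 2) {
  stopifnot(is(s, "StructureSet"))
  validObject(s)
  st <- s@structures
  iso <- s@isocenter
  centroid <- function(role) colMeans(st[[role]])
  sizeOf <- function(role) {
    p <- st[[role]]
    c(
      vol = organVolume(p, spacing), area = organSurfaceArea(p, spacing),
      diam = organDiameter(p, spacing)
    )
  }
  szBrain <- sizeOf("BRAIN_CTV")
  szEye <- (sizeOf("EYE_L") + sizeOf("EYE_R")) / 2
  szLens <- (sizeOf("LENS_L") + sizeOf("LENS_R")) / 2

  cB <- centroid("BRAIN_CTV")
  cEL <- centroid("EYE_L")
  cER <- centroid("EYE_R")
  cLL <- centroid("LENS_L")
  cLR <- centroid("LENS_R")
  d <- function(a, b) sqrt(sum((a - b)^2)) / 10 # mm -> cm

  # isocenter placed exactly at an organ centroid leaves the direction
  # undefined; map that degenerate case to zero angles instead of failing
  anglesOf <- function(ctr) {
    if (sqrt(sum((ctr - iso)^2)) < 1e-9) {
      return(c(polar = 0, azimuth = 0))
    }
    isoSphericalAngles(ctr, iso)
  }
  aB <- anglesOf(cB)
  aE <- (anglesOf(cEL) + anglesOf(cER)) / 2
  aL <- (anglesOf(cLL) + anglesOf(cLR)) / 2

  out <- c(
    Volume_Brain = unname(szBrain["vol"]),
    Volume_Eye = unname(szEye["vol"]),
    Volume_Lens = unname(szLens["vol"]),
    SurfaceArea_Brain = unname(szBrain["area"]),
    SurfaceArea_Eye = unname(szEye["area"]),
    SurfaceArea_Lens = unname(szLens["area"]),
    Diameter_Brain = unname(szBrain["diam"]),
    Diameter_Eye = unname(szEye["diam"]),
    Diameter_Lens = unname(szLens["diam"]),
    Brain_Eye = (d(cB, cEL) + d(cB, cER)) / 2,
    Brain_Lens = (d(cB, cLL) + d(cB, cLR)) / 2,
    Eye_Lens = (d(cEL, cLL) + d(cER, cLR)) / 2, # same-side pairing
    Brain_Iso = d(cB, iso),
    Eye_Iso = (d(cEL, iso) + d(cER, iso)) / 2,
    Lens_Iso = (d(cLL, iso) + d(cLR, iso)) / 2,
    Brain_Iso_Pol = unname(aB["polar"]),
    Eye_Iso_Pol = unname(aE["polar"]),
    Lens_Iso_Pol = unname(aL["polar"]),
    Brain_Iso_Azm = unname(aB["azimuth"]),
    Eye_Iso_Azm = unname(aE["azimuth"]),
    Lens_Iso_Azm = unname(aL["azimuth"])
  )
  out <- out[featureRegistry()]
  if (any(!is.finite(out))) {
    stop("non-finite feature value(s): ", paste(names(out)[!is.finite(out)], collapse = ", "))
  }
  out
}

#' Restrict a feature vector or matrix to a named subset
#'
#' @param v Named numeric vector (one case) or a [FeatureMatrix-class].
#' @param subset Character vector of canonical feature names
#'   (default [selectedFeatureNames()]).
#' @return Object of the same kind restricted to `subset`, in `subset` order.
#' @export
selectFeatures <- function(v, subset = selectedFeatureNames()) {
  if (is(v, "FeatureMatrix")) {
    unknown <- setdiff(subset, colnames(v@values))
    if (length(unknown) > 0) stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
    out <- featureMatrix(v@values[, subset, drop = FALSE], caseIds = v@caseIds)
    if (v@standardized) {
      out@center <- v@center[subset]
      out@scale <- v@scale[subset]
      out@standardized <- TRUE
    }
    return(out)
  }
  unknown <- setdiff(subset, names(v))
  if (length(unknown) > 0) stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  v[subset]
}

#' Build a FeatureMatrix from a list of structure sets
#'
#' @param cases List of [StructureSet-class] objects.
#' @param subset Optional feature-name subset (default: all 21).
#' @param spacing Slice width (mm) for the geometry integrators.
#' @return A [FeatureMatrix-class].
#' @export
featureMatrixFromCases <- function(cases, subset = NULL, spacing = 2) {
  rows <- lapply(cases, extractFeatures, spacing = spacing)
  m <- do.call(rbind, rows)
  ids <- vapply(cases, caseId, character(1))
  fm <- featureMatrix(m, caseIds = ids)
  if (!is.null(subset)) selectFeatures(fm, subset) else fm
}

#' Standardize a feature matrix (z-score)
#'
#' Column means and standard deviations are estimated on `fitRows` only and
#' stored in the returned object so new cases can be transformed with the
#' same record (leakage-safe cross-validation refits this inside each fold).
#'
#' @param m A [FeatureMatrix-class] (raw).
#' @param fitRows Row indices used to estimate center/scale (default: all).
#' @return A standardized [FeatureMatrix-class].
#' @export
standardizeFeatures <- function(m, fitRows = seq_len(nrow(m@values))) {
  stopifnot(is(m, "FeatureMatrix"))
  if (length(fitRows) == 0) stop("fitRows must be non-empty")
  sub <- m@values[fitRows, , drop = FALSE]
  ctr <- colMeans(sub)
  scl <- apply(sub, 2, stats::sd)
  bad <- colnames(sub)[!is.finite(scl) | scl < 1e-12]
  if (length(bad) > 0) {
    stop("zero-variance column(s) within fit rows: ", paste(bad, collapse = ", "))
  }
  vals <- sweep(sweep(m@values, 2, ctr), 2, scl, "/")
  out <- featureMatrix(vals, caseIds = m@caseIds)
  out@center <- ctr
  out@scale <- scl
  out@standardized <- TRUE
  validObject(out)
  out
}

#' Apply a stored standardization record to new cases
#'
#' @param record `list(center, scale)` as returned by
#'   [standardizationRecord()].
#' @param x Named numeric vector or matrix of raw feature values.
#' @return Standardized values, `(x - center) / scale` column-wise.
#' @export
applyStandardization <- function(record, x) {
  if (is.null(record$center) || is.null(record$scale)) {
    stop("invalid standardization record (needs center and scale)")
  }
  ctr <- record$center
  scl <- record$scale
  if (is.matrix(x)) {
    if (!is.null(names(ctr)) && !is.null(colnames(x))) {
      ctr <- ctr[colnames(x)]
      scl <- scl[colnames(x)]
    }
    sweep(sweep(x, 2, ctr), 2, scl, "/")
  } else {
    if (!is.null(names(ctr)) && !is.null(names(x))) {
      ctr <- ctr[names(x)]
      scl <- scl[names(x)]
    }
    (x - ctr) / scl
  }
}

#' Write / read feature matrices as CSV with a case_id column
#'
#' The standardization record, when present, is written to a JSON sidecar
#' `<path>.std.json` and restored on read.
#'
#' @param m A [FeatureMatrix-class].
#' @param path CSV file path.
#' @return `path` (write) or a [FeatureMatrix-class] (read).
#' @export
writeFeatureCSV <- function(m, path) {
  stopifnot(is(m, "FeatureMatrix"))
  df <- data.frame(case_id = m@caseIds, m@values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (m@standardized) {
    jsonlite::write_json(
      list(center = as.list(m@center), scale = as.list(m@scale)),
      paste0(path, ".std.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"case_id" %in% names(df)) stop("feature CSV must contain a case_id column")
  ids <- as.character(df$case_id)
  vals <- as.matrix(df[, setdiff(names(df), "case_id"), drop = FALSE])
  fm <- featureMatrix(vals, caseIds = ids)
  sidecar <- paste0(path, ".std.json")
  if (file.exists(sidecar)) {
    rec <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fm@center <- unlist(rec$center)[colnames(vals)]
    fm@scale <- unlist(rec$scale)[colnames(vals)]
    fm@standardized <- TRUE
  }
  fm
}
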