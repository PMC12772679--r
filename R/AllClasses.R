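#' Canonical structure roles
#'
#' The five anatomical roles a plannable whole-brain RT case must provide:
#' the brain CTV, both eyes and both lenses.
#'
#' @return Character vector of the five canonical role names.
#' @export
structureRoles <- function() {
  c("BRAIN_CTV", "EYE_L", "EYE_R", "LENS_L", "LENS_R")
}

.oarRoles <- function() c("EYE_L", "EYE_R", "LENS_L", "LENS_R")

#' StructureSet: named anatomical structures plus isocenter
#'
#' Point clouds (contour vertices) for each canonical role, in DICOM LPS
#' patient coordinates, millimetres. Coordinates are continuous; no voxel
#' indexing happens at this layer.
#'
#' @slot structures Named list of n x 3 numeric matrices (columns x, y, z in
#'   mm, LPS), one per canonical role.
#' @slot isocenter Numeric length-3 vector (mm, LPS).
#' @slot frame Coordinate-system tag; always `"LPS"`.
#' @slot caseId Opaque case identifier.
#' @export
setClass("StructureSet",
  representation(
    structures = "list",
    isocenter = "numeric",
    frame = "character",
    caseId = "character"
  ),
  prototype(frame = "LPS", caseId = "case")
)

setValidity("StructureSet", function(object) {
  msgs <- character(0)
  roles <- structureRoles()
  missing <- setdiff(roles, names(object@structures))
  if (length(missing) > 0) {
    msgs <- c(msgs, paste0("missing structure role(s): ", paste(missing, collapse = ", ")))
  }
  for (nm in intersect(roles, names(object@structures))) {
    m <- object@structures[[nm]]
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) < 1 || !is.numeric(m)) {
      msgs <- c(msgs, paste0("structure ", nm, " must be a non-empty numeric n x 3 matrix"))
    } else if (!all(is.finite(m))) {
      msgs <- c(msgs, paste0("structure ", nm, " contains non-finite coordinates"))
    }
  }
  if (length(object@isocenter) != 3 || !all(is.finite(object@isocenter))) {
    msgs <- c(msgs, "isocenter must be a finite length-3 vector")
  }
  if (!identical(object@frame, "LPS")) {
    msgs <- c(msgs, "frame must be 'LPS'")
  }
  # lateral pairing: eye centroids sit on opposite sides of the isocenter x-plane
  if (length(msgs) == 0) {
    exl <- mean(object@structures[["EYE_L"]][, 1]) - object@isocenter[1]
    exr <- mean(object@structures[["EYE_R"]][, 1]) - object@isocenter[1]
    if (!(exl > 0 && exr < 0)) {
      msgs <- c(msgs, "EYE_L must lie left (+x) and EYE_R right (-x) of the isocenter in LPS")
    }
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Construct a StructureSet
#'
#' @param structures Named list of n x 3 coordinate matrices (mm, LPS); must
#'   contain all five canonical roles (see [structureRoles()]).
#' @param isocenter Length-3 numeric (mm). If `NULL`, falls back to the brain
#'   centroid with a warning (the fixture/RTSTRUCT may not carry one).
#' @param caseId Case identifier string.
#' @return A [StructureSet-class] object.
#' @export
structureSet <- function(structures, isocenter = NULL, caseId = "case") {
  if (length(structures) == 0) stop("structures map is empty")
  structures <- lapply(structures, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y", "z")
    m
  })
  if (is.null(isocenter)) {
    if (!"BRAIN_CTV" %in% names(structures)) {
      stop("cannot derive isocenter: no BRAIN_CTV structure")
    }
    isocenter <- colMeans(structures[["BRAIN_CTV"]])
    warning("no isocenter provided; falling back to brain centroid", call. = FALSE)
  }
  new("StructureSet",
    structures = structures,
    isocenter = as.numeric(isocenter),
    frame = "LPS", caseId = as.character(caseId)
  )
}

#' @describeIn structureSet Access the named list of structure point clouds.
#' @param x A `StructureSet`.
#' @export
structures <- function(x) {
  stopifnot(is(x, "StructureSet"))
  x@structures
}

#' @describeIn structureSet Access one structure's point cloud by role.
#' @param role Canonical role name.
#' @export
structurePoints <- function(x, role) {
  stopifnot(is(x, "StructureSet"))
  if (!role %in% names(x@structures)) stop("unknown structure role: ", role)
  x@structures[[role]]
}

#' @describeIn structureSet Access the isocenter (mm, LPS).
#' @export
isocenter <- function(x) {
  stopifnot(is(x, "StructureSet"))
  x@isocenter
}

#' @describeIn structureSet Access the case identifier.
#' @export
caseId <- function(x) {
  stopifnot(is(x, "StructureSet"))
  x@caseId
}

setMethod("show", "StructureSet", function(object) {
  cat("StructureSet '", object@caseId, "' (", object@frame, ", mm)\n", sep = "")
  for (nm in names(object@structures)) {
    cat(sprintf("  %-9s %5d points\n", nm, nrow(object@structures[[nm]])))
  }
  cat(sprintf(
    "  isocenter (%.1f, %.1f, %.1f)\n",
    object@isocenter[1], object@isocenter[2], object@isocenter[3]
  ))
})

#' FeatureMatrix: cases x geometric features with a standardization record
#'
#' @slot values Numeric matrix, rows = cases, columns = named features.
#' @slot caseIds Character vector of row identifiers.
#' @slot center,scale Per-column standardization statistics (empty until
#'   [standardizeFeatures()] is applied).
#' @slot standardized Logical flag.
#' @export
setClass("FeatureMatrix",
  representation(
    values = "matrix",
    caseIds = "character",
    center = "numeric",
    scale = "numeric",
    standardized = "logical"
  ),
  prototype(standardized = FALSE, center = numeric(0), scale = numeric(0))
)

setValidity("FeatureMatrix", function(object) {
  msgs <- character(0)
  if (is.null(colnames(object@values))) msgs <- c(msgs, "feature columns must be named")
  if (length(object@caseIds) != nrow(object@values)) {
    msgs <- c(msgs, "caseIds length must equal the number of rows")
  }
  if (object@standardized) {
    if (length(object@center) != ncol(object@values) ||
      length(object@scale) != ncol(object@values)) {
      msgs <- c(msgs, "standardized matrix must carry per-column center and scale")
    }
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Construct a FeatureMatrix from a matrix or data frame
#'
#' @param values Numeric matrix or data frame (rows = cases, named columns).
#' @param caseIds Optional row identifiers; defaults to rownames or `case<i>`.
#' @return A [FeatureMatrix-class].
#' @export
featureMatrix <- function(values, caseIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(caseIds)) {
    caseIds <- if (!is.null(rownames(values))) rownames(values) else paste0("case", seq_len(nrow(values)))
  }
  rownames(values) <- caseIds
  new("FeatureMatrix", values = values, caseIds = as.character(caseIds))
}

#' @describeIn featureMatrix Extract the numeric matrix.
#' @param x A `FeatureMatrix`.
#' @export
featureValues <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  x@values
}

#' @describeIn featureMatrix The standardization record (`list(center, scale)`),
#'   or `NULL` if the matrix is not standardized.
#' @export
standardizationRecord <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  if (!x@standardized) {
    return(NULL)
  }
  list(center = x@center, scale = x@scale)
}

#' @describeIn featureMatrix Whether the matrix has been standardized.
#' @export
isStandardized <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  isTRUE(x@standardized)
}

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf(
    "FeatureMatrix: %d cases x %d features%s\n",
    nrow(object@values), ncol(object@values),
    if (object@standardized) " (standardized)" else ""
  ))
  cat("  features:", paste(utils::head(colnames(object@values), 6), collapse = ", "),
    if (ncol(object@values) > 6) ", ..." else "", "\n",
    sep = ""
  )
})

#' Auto-FiF hyperparameter settings
#'
#' The four searched settings plus the two fixed defaults of the Auto-FiF
#' planning function. Coverage priority takes values 25/50/75/100 (%),
#' number of subfields 1-3, minimum segment MU per fraction 2/4/6/8 and
#' minimum segment area 4/6/9/10 cm^2. The classifier label space restricts
#' (MU, area) to the four clinically used combinations (2,4), (4,6), (6,9),
#' (8,10); the labeling grid search may visit the full crossing.
#'
#' @slot coveragePriority numeric, percent.
#' @slot nSubfields numeric, count.
#' @slot minSegmentMU numeric, MU per fraction.
#' @slot minSegmentArea numeric, cm^2.
#' @slot openLeafPairs numeric, fixed default 1.
#' @slot leafEndSeparation numeric, fixed default 0 cm.
#' @export
setClass("AutoFifHyperparameters",
  representation(
    coveragePriority = "numeric",
    nSubfields = "numeric",
    minSegmentMU = "numeric",
    minSegmentArea = "numeric",
    openLeafPairs = "numeric",
    leafEndSeparation = "numeric"
  ),
  prototype(openLeafPairs = 1, leafEndSeparation = 0)
)

setValidity("AutoFifHyperparameters", function(object) {
  msgs <- character(0)
  if (!object@coveragePriority %in% c(25, 50, 75, 100)) {
    msgs <- c(msgs, "coveragePriority must be one of 25, 50, 75, 100")
  }
  if (!object@nSubfields %in% c(1, 2, 3)) {
    msgs <- c(msgs, "nSubfields must be 1, 2 or 3")
  }
  if (!object@minSegmentMU %in% c(2, 4, 6, 8)) {
    msgs <- c(msgs, "minSegmentMU must be one of 2, 4, 6, 8")
  }
  if (!object@minSegmentArea %in% c(4, 6, 9, 10)) {
    msgs <- c(msgs, "minSegmentArea must be one of 4, 6, 9, 10")
  }
  if (!identical(object@openLeafPairs, 1)) {
    msgs <- c(msgs, "openLeafPairs is fixed at 1")
  }
  if (!identical(object@leafEndSeparation, 0)) {
    msgs <- c(msgs, "leafEndSeparation is fixed at 0 cm")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Construct Auto-FiF hyperparameters
#'
#' @param coveragePriority Target coverage priority in percent (25/50/75/100).
#' @param nSubfields Number of subfields (1-3).
#' @param minSegmentMU Minimum segment MU per fraction (2/4/6/8).
#' @param minSegmentArea Minimum segment area in cm^2 (4/6/9/10).
#' @return An [AutoFifHyperparameters-class] object. The fixed defaults
#'   (1 open leaf pair, 0 cm leaf end separation) are attached automatically.
#' @export
autoFifHyperparameters <- function(coveragePriority, nSubfields, minSegmentMU, minSegmentArea) {
  new("AutoFifHyperparameters",
    coveragePriority = as.numeric(coveragePriority),
    nSubfields = as.numeric(nSubfields),
    minSegmentMU = as.numeric(minSegmentMU),
    minSegmentArea = as.numeric(minSegmentArea),
    openLeafPairs = 1, leafEndSeparation = 0
  )
}

#' @describeIn autoFifHyperparameters Coverage priority (percent).
#' @param x An `AutoFifHyperparameters`.
#' @export
coveragePriority <- function(x) x@coveragePriority

#' @describeIn autoFifHyperparameters Number of subfields.
#' @export
nSubfields <- function(x) x@nSubfields

#' @describeIn autoFifHyperparameters (MU, area) pair.
#' @export
muArea <- function(x) c(mu = x@minSegmentMU, area = x@minSegmentArea)

setMethod("show", "AutoFifHyperparameters", function(object) {
  cat(sprintf(
    "AutoFifHyperparameters: priority %g%%, %g subfield(s), min MU %g, min area %g cm^2 (leaf pairs 1, end sep 0 cm)\n",
    object@coveragePriority, object@nSubfields, object@minSegmentMU, object@minSegmentArea
  ))
})

#' PlanResult: one surrogate Auto-FiF plan
#'
#' Per-structure voxel doses sampled on a regular grid aligned to the
#' structure set, plus the hyperparameters and prescription used. The dose
#' model is a synthetic surrogate for a treatment planning system and is
#' labeled as such in every export.
#'
#' @slot structureDose Named list (per role) of numeric voxel dose vectors (Gy).
#' @slot voxelVolume Voxel volume (cm^3).
#' @slot spacing Grid spacing (mm).
#' @slot hyperparameters The [AutoFifHyperparameters-class] used.
#' @slot prescription Prescription dose (Gy).
#' @slot seed Integer seed that fixed the surrogate heterogeneity pattern.
#' @slot engine Engine tag (e.g. `"surrogate-fif"`).
#' @export
setClass("PlanResult",
  representation(
    structureDose = "list",
    voxelVolume = "numeric",
    spacing = "numeric",
    hyperparameters = "AutoFifHyperparameters",
    prescription = "numeric",
    seed = "numeric",
    engine = "character"
  )
)

setValidity("PlanResult", function(object) {
  msgs <- character(0)
  missing <- setdiff(structureRoles(), names(object@structureDose))
  if (length(missing) > 0) {
    msgs <- c(msgs, paste0("dose missing for role(s): ", paste(missing, collapse = ", ")))
  }
  for (nm in names(object@structureDose)) {
    d <- object@structureDose[[nm]]
    if (length(d) == 0) msgs <- c(msgs, paste0("empty dose vector for ", nm))
    if (any(!is.finite(d)) || any(d < 0)) {
      msgs <- c(msgs, paste0("dose for ", nm, " must be finite and non-negative"))
    }
  }
  if (object@prescription <= 0) msgs <- c(msgs, "prescription must be positive")
  if (length(msgs) == 0) TRUE else msgs
})

#' @describeIn autoFifHyperparameters Hyperparameters attached to a plan.
#' @export
planHyperparameters <- function(x) {
  stopifnot(is(x, "PlanResult"))
  x@hyperparameters
}

#' Per-structure voxel doses of a plan
#'
#' @param x A [PlanResult-class].
#' @param role Optional role; if given, that structure's dose vector.
#' @return Named list of dose vectors, or one vector.
#' @export
structureDose <- function(x, role = NULL) {
  stopifnot(is(x, "PlanResult"))
  if (is.null(role)) {
    return(x@structureDose)
  }
  if (!role %in% names(x@structureDose)) stop("no dose for role: ", role)
  x@structureDose[[role]]
}

setMethod("show", "PlanResult", function(object) {
  cat(sprintf(
    "PlanResult [%s] prescription %.1f Gy, %.0f mm grid\n",
    object@engine, object@prescription, object@spacing
  ))
  show(object@hyperparameters)
  m <- dvhMetrics(object)
  cat(sprintf(
    "  CTV D1%%/D95%%/D99%%: %.2f / %.2f / %.2f Gy\n",
    m[["D1_BRAIN_CTV"]], m[["D95_BRAIN_CTV"]], m[["D99_BRAIN_CTV"]]
  ))
})

#' FeatureDendrogram: agglomerative clustering of feature columns
#'
#' @slot merge,height Merge structure and heights as in [stats::hclust()].
#' @slot labels Leaf (feature) names.
#' @slot linkage Linkage criterion used.
#' @slot tree The underlying `hclust` object.
#' @export
setClass("FeatureDendrogram",
  representation(
    merge = "matrix",
    height = "numeric",
    labels = "character",
    linkage = "character",
    tree = "ANY"
  )
)

setValidity("FeatureDendrogram", function(object) {
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1 || length(object@height) != n - 1) {
    return("a dendrogram over n leaves must contain exactly n - 1 merges")
  }
  TRUE
})

setMethod("show", "FeatureDendrogram", function(object) {
  cat(sprintf(
    "FeatureDendrogram: %d features, %s linkage, merge heights [%.3g, %.3g]\n",
    length(object@labels), object@linkage, min(object@height), max(object@height)
  ))
})

#' TrainedHead: one trained hyperparameter classifier head
#'
#' @slot id Head identifier: `"A"` (coverage priority, 4 classes), `"B"`
#'   (number of subfields, 3 classes) or `"C"` (joint MU/area label, 4 classes).
#' @slot spec Layer specification (list).
#' @slot weights List of weight/bias matrices.
#' @slot classes Decoded class values (in canonical ascending order).
#' @slot log Per-epoch training/validation loss data frame.
#' @slot standardization Standardization record the head expects inputs under.
#' @export
setClass("TrainedHead",
  representation(
    id = "character",
    spec = "list",
    weights = "list",
    classes = "list",
    log = "data.frame",
    standardization = "list"
  )
)

setValidity("TrainedHead", function(object) {
  expected <- c(A = 4L, B = 3L, C = 4L)
  if (!object@id %in% names(expected)) {
    return("head id must be 'A', 'B' or 'C'")
  }
  if (length(object@classes) != expected[[object@id]]) {
    return(sprintf(
      "head %s must have %d classes, found %d",
      object@id, expected[[object@id]], length(object@classes)
    ))
  }
  TRUE
})

setMethod("show", "TrainedHead", function(object) {
  cat(sprintf(
    "TrainedHead %s: %d -> %s -> %d classes (%s)\n",
    object@id, object@spec$inputDim,
    paste(object@spec$hidden, collapse = " -> "),
    length(object@classes),
    if (length(object@weights) > 0) "trained" else "untrained"
  ))
})

#' StructuredFeedback: machine-readable plan critique
#'
#' @slot targetCoverage One of `"good"`, `"bad"`, `"unchanged"`.
#' @slot oarDose One of `"good"`, `"high"`, `"unchanged"`.
#' @slot oarRoles Roles the OAR verdict applies to (empty = all OARs).
#' @slot transcript Raw critique text.
#' @slot interpreter Backend identifier.
#' @export
setClass("StructuredFeedback",
  representation(
    targetCoverage = "character",
    oarDose = "character",
    oarRoles = "character",
    transcript = "character",
    interpreter = "character"
  )
)

setValidity("StructuredFeedback", function(object) {
  msgs <- character(0)
  if (!object@targetCoverage %in% c("good", "bad", "unchanged")) {
    msgs <- c(msgs, "targetCoverage must be good/bad/unchanged")
  }
  if (!object@oarDose %in% c("good", "high", "unchanged")) {
    msgs <- c(msgs, "oarDose must be good/high/unchanged")
  }
  if (length(object@oarRoles) > 0 && !all(object@oarRoles %in% .oarRoles())) {
    msgs <- c(msgs, "oarRoles must be OAR roles (eyes/lenses)")
  }
  if (length(msgs) == 0) TRUE else msgs
})

setMethod("show", "StructuredFeedback", function(object) {
  cat(sprintf(
    "StructuredFeedback [%s]: target_coverage=%s, oar_dose=%s%s\n",
    object@interpreter, object@targetCoverage, object@oarDose,
    if (length(object@oarRoles) > 0) paste0(" (", paste(object@oarRoles, collapse = ", "), ")") else ""
  ))
})

#' Is a feedback actionable?
#'
#' Actionable means it induces at least one refinement goal: coverage judged
#' bad, or OAR dose judged high.
#'
#' @param f A [StructuredFeedback-class].
#' @return Logical.
#' @export
isActionable <- function(f) {
  stopifnot(is(f, "StructuredFeedback"))
  identical(f@targetCoverage, "bad") || identical(f@oarDose, "high")
}
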