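# Synthetic anatomy: random but plausible WBRT phantoms and labeled datasets.
#
# A phantom is an ellipsoidal brain plus spherical eyes and lenses placed
# anterior-inferior-lateral, built as per-slice contour rings (the native
# RTSTRUCT layout). Equator rings with an even point count are always
# included, so the maximum Feret diameter of each organ equals its analytic
# diameter exactly.

#' Phantom specification
#'
#' Concrete geometry for one phantom. All sizes in cm. Defaults describe a
#' mid-range adult head; [randomPhantomSpec()] draws a population around it.
#'
#' @param brainSemiAxes Length-3 semi-axes (x = lateral, y = antero-posterior,
#'   z = cranio-caudal); y must be the largest (head length dominates).
#' @param eyeRadius,lensRadius Sphere radii; the lens must be smaller than
#'   the eye.
#' @param eyeLateral Lateral offset of each eye center from the midline.
#' @param eyeGap Anterior gap between brain surface and eye center envelope.
#' @param eyeInferiorFrac Eye center depth as a fraction of the inferior
#'   brain semi-axis.
#' @param asymmetryJitter Right-side size/position jitter fraction, in
#'   `[0, 0.1]`; 0 gives an exactly mirror-symmetric phantom.
#' @param isocenterOffset Length-3 isocenter offset from the brain centroid.
#' @param sliceThickness Contour ring spacing for the brain (mm).
#' @param seed Integer seed (drives the jitter draws).
#' @return A `PhantomSpec` (classed list).
#' @export
phantomSpec <- function(brainSemiAxes = c(6.4, 8.2, 6.2),
                        eyeRadius = 1.2, lensRadius = 0.45,
                        eyeLateral = 3.1, eyeGap = 0.5, eyeInferiorFrac = 0.6,
                        asymmetryJitter = 0, isocenterOffset = c(0, 0, 0),
                        sliceThickness = 2.5, seed = 1) {
  spec <- structure(
    list(
      brainSemiAxes = brainSemiAxes, eyeRadius = eyeRadius,
      lensRadius = lensRadius, eyeLateral = eyeLateral, eyeGap = eyeGap,
      eyeInferiorFrac = eyeInferiorFrac, asymmetryJitter = asymmetryJitter,
      isocenterOffset = isocenterOffset, sliceThickness = sliceThickness,
      seed = as.integer(seed)
    ),
    class = "PhantomSpec"
  )
  validatePhantomSpec(spec)
  spec
}

validatePhantomSpec <- function(spec) {
  if (any(c(
    spec$brainSemiAxes, spec$eyeRadius, spec$lensRadius,
    spec$eyeLateral, spec$eyeGap, spec$sliceThickness
  ) <= 0)) {
    stop("all phantom sizes must be positive")
  }
  if (spec$asymmetryJitter < 0 || spec$asymmetryJitter > 0.1) {
    stop("asymmetryJitter must be in [0, 0.1]")
  }
  if (spec$lensRadius >= spec$eyeRadius) {
    stop("lens must be smaller than the eye")
  }
  if (spec$brainSemiAxes[2] < max(spec$brainSemiAxes)) {
    stop("the antero-posterior semi-axis (y) must be the largest")
  }
  invisible(spec)
}

#' Draw a population-plausible phantom specification
#'
#' Size ranges (documented constants, not fitted to any cohort): brain
#' antero-posterior diameter 14-18.8 cm, eye diameter 2.2-2.6 cm, lens
#' diameter 0.8-1.1 cm, isocenter within 5 mm of the brain centroid, lateral
#' asymmetry jitter up to 3%.
#'
#' @param seed Integer seed.
#' @return A `PhantomSpec`.
#' @export
randomPhantomSpec <- function(seed = 1) {
  withSeed(seed, {
    ay <- stats::runif(1, 7.0, 9.4)
    ax <- stats::runif(1, 5.6, min(7.2, ay - 0.2))
    az <- stats::runif(1, 5.4, min(7.0, ay - 0.2))
    phantomSpec(
      brainSemiAxes = c(ax, ay, az),
      eyeRadius = stats::runif(1, 1.1, 1.3),
      lensRadius = stats::runif(1, 0.40, 0.55),
      eyeLateral = stats::runif(1, 2.8, 3.4),
      eyeGap = stats::runif(1, 0.3, 0.8),
      eyeInferiorFrac = stats::runif(1, 0.5, 0.7),
      asymmetryJitter = stats::runif(1, 0, 0.03),
      isocenterOffset = stats::runif(3, -0.5, 0.5),
      seed = seed
    )
  })
}

# Contour rings of an axis-aligned ellipsoid (semi-axes a, b, c in mm),
# centered at `center`. Includes the equator plane; even point counts put
# antipodal vertices on each ring.
ellipsoidRings <- function(center, a, b, c, dz = 2.5) {
  nHalf <- max(7L, ceiling(0.98 * c / dz))
  zs <- unique(c(-rev(seq_len(nHalf)), 0, seq_len(nHalf))) / nHalf * 0.98 * c
  rings <- lapply(zs, function(z) {
    s <- sqrt(max(0, 1 - (z / c)^2))
    if (s < 1e-6) {
      return(NULL)
    }
    n <- max(12L, 4L * ceiling(pi * max(a, b) * s / 16)) # multiple of 4: keeps
    # antipodal vertices on both principal axes of every ring
    th <- 2 * pi * (seq_len(n) - 1) / n
    cbind(center[1] + a * s * cos(th), center[2] + b * s * sin(th), center[3] + z)
  })
  m <- do.call(rbind, rings[!vapply(rings, is.null, logical(1))])
  colnames(m) <- c("x", "y", "z")
  m
}

sphereRings <- function(center, r, dz = 1.2) {
  ellipsoidRings(center, r, r, r, dz = dz)
}

#' Generate a phantom structure set
#'
#' Deterministic given the spec (including its seed, which drives the
#' lateral-asymmetry jitter). Zero jitter yields exactly mirror-symmetric
#' eyes and lenses.
#'
#' @param spec A [phantomSpec()].
#' @return A [StructureSet-class] (mm, LPS; brain centroid at the origin).
#' @export
generatePhantom <- function(spec) {
  validatePhantomSpec(spec)
  ax <- spec$brainSemiAxes[1] * 10
  ay <- spec$brainSemiAxes[2] * 10
  az <- spec$brainSemiAxes[3] * 10
  rEye <- spec$eyeRadius * 10
  rLens <- spec$lensRadius * 10
  j <- spec$asymmetryJitter
  jit <- withSeed(spec$seed, {
    list(
      eyeR = stats::runif(1, -j, j), lensR = stats::runif(1, -j, j),
      eyeShift = stats::runif(3, -j, j) * 50, # up to 0.5 mm/% of jitter
      lensShift = stats::runif(3, -j, j) * 30
    )
  })

  brain <- ellipsoidRings(c(0, 0, 0), ax, ay, az, dz = spec$sliceThickness)
  ez <- -spec$eyeInferiorFrac * az
  eyeY <- -(ay * sqrt(max(0, 1 - (ez / az)^2)) + spec$eyeGap * 10 + rEye)
  eyeLC <- c(spec$eyeLateral * 10, eyeY, ez)
  eyeL <- sphereRings(eyeLC, rEye)
  lensLC <- eyeLC + c(0, -(rEye - rLens), 0) # anterior pole, inside the eye
  lensL <- sphereRings(lensLC, rLens, dz = 0.8)

  # right side: mirror of the left, with optional size/position jitter
  mirror <- function(m) {
    m[, 1] <- -m[, 1]
    m
  }
  if (j == 0) {
    eyeR <- mirror(eyeL)
    lensR <- mirror(lensL)
  } else {
    eyeRC <- c(-eyeLC[1], eyeLC[2], eyeLC[3]) + jit$eyeShift
    eyeR <- sphereRings(eyeRC, rEye * (1 + jit$eyeR))
    lensRC <- eyeRC + c(0, -(rEye * (1 + jit$eyeR) - rLens * (1 + jit$lensR)), 0) + jit$lensShift
    lensR <- sphereRings(lensRC, rLens * (1 + jit$lensR), dz = 0.8)
  }

  structureSet(
    list(
      BRAIN_CTV = brain, EYE_L = eyeL, EYE_R = eyeR,
      LENS_L = lensL, LENS_R = lensR
    ),
    isocenter = spec$isocenterOffset * 10,
    caseId = sprintf("phantom%06d", spec$seed)
  )
}

# Frozen thresholds of the geometry -> label rule: population quantiles of
# the measured features under the default PhantomSpec ranges (one-off
# 1500-draw estimate at design time), so the rule's classes are balanced.
# The margins define a guard band around each threshold: labeled-dataset
# draws falling inside a band are redrawn, so the benchmark's labels are
# unambiguous (boundary cases would otherwise be unresolvable at any
# training size and say nothing about parameter recovery).
.RULE_THRESHOLDS <- list(
  eyeIso = c(9.155, 9.572, 10.053), # cm; quartiles of Eye_Iso
  brainDiam = c(15.537, 17.220), # cm; terciles of Diameter_Brain
  lensDiam = c(0.8763, 0.9482, 1.0221) # cm; quartiles of Diameter_Lens
)
.RULE_MARGINS <- list(eyeIso = 0.08, brainDiam = 0.15, lensDiam = 0.012)

# TRUE when every rule feature is clear of its thresholds by the margin.
ruleUnambiguous <- function(features) {
  th <- .RULE_THRESHOLDS
  mg <- .RULE_MARGINS
  all(abs(features[["Eye_Iso"]] - th$eyeIso) > mg$eyeIso) &&
    all(abs(features[["Diameter_Brain"]] - th$brainDiam) > mg$brainDiam) &&
    all(abs(features[["Diameter_Lens"]] - th$lensDiam) > mg$lensDiam)
}

#' The geometry-to-label rule for synthetic supervision
#'
#' A deterministic, monotone rule on raw features: coverage priority
#' increases as the eyes approach the isocenter (Eye_Iso quartiles, closest
#' quartile = 100%), the number of subfields increases with brain diameter
#' (terciles), and the (MU, area) combo follows the lens diameter quartile.
#' The driving features are among the selected ten, so planted-feature
#' recovery is testable end to end.
#'
#' @param features A 21-feature vector from [extractFeatures()].
#' @return An [AutoFifHyperparameters-class].
#' @export
labelRule <- function(features) {
  th <- .RULE_THRESHOLDS
  prioIdx <- 4 - findInterval(features[["Eye_Iso"]], th$eyeIso) # close eyes -> high priority
  nsub <- findInterval(features[["Diameter_Brain"]], th$brainDiam) + 1
  comboIdx <- findInterval(features[["Diameter_Lens"]], th$lensDiam) + 1
  combo <- .MU_AREA_COMBOS[[comboIdx]]
  autoFifHyperparameters(c(25, 50, 75, 100)[prioIdx], nsub, combo[1], combo[2])
}

#' Generate a rule-labeled synthetic dataset
#'
#' Draws `n` random phantoms, extracts their features, labels them with
#' [labelRule()], and optionally flips each head's label independently with
#' probability `noise` (to a uniformly drawn different class). Draws whose
#' rule features fall within the guard band of a class threshold are redrawn
#' (deterministically), so every shipped label is unambiguous. A class
#' balance report is attached as attribute `classBalance`.
#'
#' @param n Number of cases (>= 1).
#' @param noise Label-flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return List of labeled cases; each has `structureSet`,
#'   `hyperparameters`, `features` (the 21 raw features) and `provenance`.
#' @export
generateLabeledDataset <- function(n, noise = 0, seed = 1) {
  stopifnot(n >= 1, noise >= 0, noise < 0.5)
  draws <- withSeed(seed, {
    list(
      caseSeeds = sample.int(2^30, n),
      flip = matrix(stats::runif(3 * n), n, 3),
      alt = matrix(stats::runif(3 * n), n, 3)
    )
  })
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    caseSeed <- draws$caseSeeds[i]
    repeat {
      sp <- randomPhantomSpec(caseSeed)
      ph <- generatePhantom(sp)
      feats <- extractFeatures(ph)
      if (ruleUnambiguous(feats)) break
      caseSeed <- (caseSeed + 7919L) %% 2147483629L # deterministic redraw
    }
    h <- labelRule(feats)
    flipped <- FALSE
    if (noise > 0) {
      enc <- c(
        encodeHeadLabel("A", h@coveragePriority),
        encodeHeadLabel("B", h@nSubfields),
        encodeHeadLabel("C", muArea(h))
      )
      sizes <- c(4, 3, 4)
      for (hd in 1:3) {
        if (draws$flip[i, hd] < noise) {
          flipped <- TRUE
          others <- setdiff(seq_len(sizes[hd]), enc[hd])
          enc[hd] <- others[ceiling(draws$alt[i, hd] * length(others))]
        }
      }
      combo <- decodeHeadLabel("C", enc[3])
      h <- autoFifHyperparameters(
        decodeHeadLabel("A", enc[1]), decodeHeadLabel("B", enc[2]),
        combo[1], combo[2]
      )
    }
    cases[[i]] <- list(
      structureSet = ph, hyperparameters = h, features = feats,
      provenance = if (flipped) "rule:geometry+flip" else "rule:geometry"
    )
  }
  attr(cases, "classBalance") <- list(
    coveragePriority = table(vapply(cases, function(cs) cs$hyperparameters@coveragePriority, numeric(1))),
    nSubfields = table(vapply(cases, function(cs) cs$hyperparameters@nSubfields, numeric(1))),
    muArea = table(vapply(cases, function(cs) paste(muArea(cs$hyperparameters), collapse = ","), character(1)))
  )
  cases
}

#' Generate a closed-loop dataset with surrogate reference plans
#'
#' For each phantom, hyperparameters are drawn uniformly from the restricted
#' label space (4 priorities x 3 subfields x 4 clinical combos) and the
#' reference plan is generated by the engine at those settings, so
#' [gridLabelSearch()] recovery is testable end to end.
#'
#' @param n Number of cases.
#' @param engine A [tpsAdapter()] (default [surrogateEngine()]).
#' @param seed Integer seed.
#' @param prescription Prescription dose (Gy).
#' @return List of cases with `structureSet`, `hyperparameters`,
#'   `referencePlan`, `seed` and `provenance`.
#' @export
generateClosedLoopDataset <- function(n, engine = surrogateEngine(), seed = 1,
                                      prescription = 30) {
  draws <- withSeed(seed, {
    list(
      caseSeeds = sample.int(2^30, n),
      prio = sample(c(25, 50, 75, 100), n, replace = TRUE),
      nsub = sample(1:3, n, replace = TRUE),
      combo = sample(1:4, n, replace = TRUE)
    )
  })
  lapply(seq_len(n), function(i) {
    ph <- generatePhantom(randomPhantomSpec(draws$caseSeeds[i]))
    combo <- .MU_AREA_COMBOS[[draws$combo[i]]]
    h <- autoFifHyperparameters(draws$prio[i], draws$nsub[i], combo[1], combo[2])
    ref <- engine$generatePlan(ph, h, prescription, draws$caseSeeds[i])
    list(
      structureSet = ph, hyperparameters = h, referencePlan = ref,
      seed = draws$caseSeeds[i], provenance = "closed-loop"
    )
  })
}

#' Export / import a labeled dataset as plain-text fixtures
#'
#' Writes one fixture file per case plus a `labels.csv` (case id, file,
#' hyperparameters). `loadLabeledDataset` reverses the export, recomputing
#' features.
#'
#' @param cases Output of [generateLabeledDataset()].
#' @param dir Output directory (created if needed).
#' @return The directory (export) or a case list (import).
#' @export
saveDatasetFixtures <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cases, function(cs) {
    fn <- paste0(caseId(cs$structureSet), ".txt")
    saveFixture(cs$structureSet, file.path(dir, fn))
    h <- cs$hyperparameters
    data.frame(
      case_id = caseId(cs$structureSet), file = fn,
      coveragePriority = h@coveragePriority, nSubfields = h@nSubfields,
      minSegmentMU = h@minSegmentMU, minSegmentArea = h@minSegmentArea
    )
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname saveDatasetFixtures
#' @export
loadLabeledDataset <- function(dir) {
  labels <- utils::read.csv(file.path(dir, "labels.csv"))
  lapply(seq_len(nrow(labels)), function(i) {
    s <- loadFixture(file.path(dir, labels$file[i]))
    list(
      structureSet = s,
      hyperparameters = autoFifHyperparameters(
        labels$coveragePriority[i], labels$nSubfields[i],
        labels$minSegmentMU[i], labels$minSegmentArea[i]
      ),
      features = extractFeatures(s),
      provenance = "fixture"
    )
  })
}
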