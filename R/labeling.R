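# Grid-search ground-truth labeling: find the hyperparameter setting whose
# plan best reproduces a reference ("physician-approved") plan.

#' The Auto-FiF hyperparameter grid
#'
#' Full grid: 4 coverage priorities x 3 subfield counts x 4 MU levels x
#' 4 area levels = 192 configurations. Restricted grid: the 4 clinical
#' (MU, area) combos instead of the 4 x 4 crossing = 48 configurations.
#'
#' @param restricted Use the 4 clinical (MU, area) combos only.
#' @return Data frame with columns `coveragePriority`, `nSubfields`,
#'   `minSegmentMU`, `minSegmentArea`.
#' @export
hyperparameterGrid <- function(restricted = FALSE) {
  if (restricted) {
    combos <- do.call(rbind, .MU_AREA_COMBOS)
    g <- expand.grid(
      comboIdx = seq_len(nrow(combos)),
      nSubfields = c(1, 2, 3),
      coveragePriority = c(25, 50, 75, 100)
    )
    data.frame(
      coveragePriority = g$coveragePriority,
      nSubfields = g$nSubfields,
      minSegmentMU = combos[g$comboIdx, 1],
      minSegmentArea = combos[g$comboIdx, 2]
    )
  } else {
    g <- expand.grid(
      minSegmentArea = .AREA_LEVELS,
      minSegmentMU = .MU_LEVELS,
      nSubfields = c(1, 2, 3),
      coveragePriority = c(25, 50, 75, 100)
    )
    g[, c("coveragePriority", "nSubfields", "minSegmentMU", "minSegmentArea")]
  }
}

# Similarity of a candidate plan to the reference after D95 normalization:
# weighted L1 over the evaluation metric set, |dD1| + |dD99| for the CTV
# plus the sum of |d mean| over the four OARs (equal weights).
planSimilarityScore <- function(candidate, refMetrics, refD95) {
  cm <- dvhMetrics(normalizeToD95(candidate, refD95))
  keys <- c("D1_BRAIN_CTV", "D99_BRAIN_CTV", "Mean_EYE_L", "Mean_EYE_R", "Mean_LENS_L", "Mean_LENS_R")
  sum(abs(cm[keys] - refMetrics[keys]))
}

#' Grid-search labeling against a reference plan
#'
#' Exhaustively evaluates a hyperparameter grid with the engine, scores each
#' plan's similarity to the reference (weighted L1 over the evaluation
#' metric set after D95% normalization) and returns the argmin. Ties are
#' broken deterministically: fewer subfields, then lower coverage priority,
#' then lower (MU, area) strength. Engine failures on single configurations
#' are skipped with a warning; if every configuration fails, an error is
#' raised.
#'
#' @param s The case's [StructureSet-class].
#' @param reference The reference [PlanResult-class] to reproduce.
#' @param engine A [tpsAdapter()] (default [surrogateEngine()]).
#' @param grid Configuration data frame (default [hyperparameterGrid()],
#'   192 configs).
#' @param prescription Prescription in Gy (default: the reference's).
#' @param seed Engine seed (default: the reference's, as in a closed loop).
#' @return List with `best` ([AutoFifHyperparameters-class]), `score`, and
#'   `trace` (one row per configuration with its similarity score).
#' @export
gridLabelSearch <- function(s, reference, engine = surrogateEngine(),
                            grid = hyperparameterGrid(),
                            prescription = reference@prescription,
                            seed = reference@seed) {
  stopifnot(is(reference, "PlanResult"), nrow(grid) >= 1)
  refMetrics <- dvhMetrics(reference)
  refD95 <- refMetrics[["D95_BRAIN_CTV"]]
  ctx <- NULL
  if (!is.null(engine$newContext) && !is.null(engine$planFromContext)) {
    ctx <- engine$newContext(s, seed = seed)
  }
  scores <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    h <- autoFifHyperparameters(
      grid$coveragePriority[i], grid$nSubfields[i],
      grid$minSegmentMU[i], grid$minSegmentArea[i]
    )
    scores[i] <- tryCatch(
      {
        plan <- if (!is.null(ctx)) {
          engine$planFromContext(ctx, h, prescription)
        } else {
          engine$generatePlan(s, h, prescription, seed)
        }
        planSimilarityScore(plan, refMetrics, refD95)
      },
      error = function(e) {
        warning(
          "engine failed for configuration ", i, " (", conditionMessage(e),
          "); skipped",
          call. = FALSE
        )
        NA_real_
      }
    )
  }
  if (all(is.na(scores))) stop("engine failed on every grid configuration")
  strength <- mapply(muAreaStrength, grid$minSegmentMU, grid$minSegmentArea)
  ord <- order(scores, grid$nSubfields, grid$coveragePriority, strength, na.last = TRUE)
  bestIdx <- ord[1]
  list(
    best = autoFifHyperparameters(
      grid$coveragePriority[bestIdx], grid$nSubfields[bestIdx],
      grid$minSegmentMU[bestIdx], grid$minSegmentArea[bestIdx]
    ),
    score = scores[bestIdx],
    trace = data.frame(grid, score = scores)
  )
}
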