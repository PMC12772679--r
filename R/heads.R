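# The three classifier heads mapping selected geometric features to Auto-FiF
# hyperparameters:
#   A - target coverage priority (4 classes: 25/50/75/100 %)
#   B - number of subfields     (3 classes: 1/2/3)
#   C - joint (min MU, min area) label (4 classes: (2,4) (4,6) (6,9) (8,10));
#       reuses B's backbone architecture with its own output layer.
# Class orderings are frozen as the printed ranges ascending, which fixes the
# encode/decode tables once and for all.

.MU_AREA_COMBOS <- list(c(2, 4), c(4, 6), c(6, 9), c(8, 10))

#' Class decode table of a head
#'
#' @param id Head id: `"A"`, `"B"` or `"C"`.
#' @return List of class values in canonical (ascending) order: percentages
#'   for A, subfield counts for B, `(MU, area)` pairs for C.
#' @export
headClasses <- function(id) {
  switch(id,
    A = as.list(c(25, 50, 75, 100)),
    B = as.list(c(1, 2, 3)),
    C = .MU_AREA_COMBOS,
    stop("invalid head id: ", id)
  )
}

#' Encode a hyperparameter value as a class index
#'
#' @param id Head id.
#' @param value Coverage priority (A), subfield count (B), or length-2
#'   `(MU, area)` vector (C).
#' @return 1-based class index.
#' @export
encodeHeadLabel <- function(id, value) {
  classes <- headClasses(id)
  for (k in seq_along(classes)) {
    if (isTRUE(all(abs(unlist(classes[[k]]) - unlist(value)) < 1e-9))) {
      return(k)
    }
  }
  stop(
    "value ", paste(unlist(value), collapse = ","),
    " is not a valid class of head ", id
  )
}

#' @rdname encodeHeadLabel
#' @param k 1-based class index.
#' @export
decodeHeadLabel <- function(id, k) {
  classes <- headClasses(id)
  if (k < 1 || k > length(classes)) stop("class index ", k, " out of range for head ", id)
  classes[[k]]
}

#' Build an untrained classifier head
#'
#' Head A: FC(32) + LeakyReLU + dropout 0.35, FC(16) + ReLU, FC(4).
#' Heads B/C: FC(32) + LeakyReLU + dropout 0.10, FC(16) + ReLU + dropout
#' 0.15, FC(3 or 4). C shares B's backbone architecture (widths, activations,
#' dropout, optimizer settings), not its weights. Hidden widths are
#' configurable; 32 -> 16 is the default for the small-cohort regime.
#'
#' @param id Head id (`"A"`, `"B"`, `"C"`).
#' @param inputDim Number of input features (default 10, the selected subset).
#' @param hidden Hidden layer widths (length 2).
#' @return A [TrainedHead-class] with empty weights.
#' @export
buildHead <- function(id, inputDim = 10, hidden = c(32, 16)) {
  classes <- headClasses(id) # validates id
  spec <- list(
    inputDim = as.integer(inputDim),
    hidden = as.integer(hidden),
    outDim = length(classes),
    activations = c("lrelu", "relu"),
    dropout = if (id == "A") c(0.35, 0) else c(0.10, 0.15),
    lr = if (id == "A") 2e-4 else 1e-3,
    weightDecay = if (id == "A") 2e-4 else 9e-5
  )
  new("TrainedHead",
    id = id, spec = spec, weights = list(),
    classes = classes, log = data.frame(), standardization = list()
  )
}

# Encode a label vector for a head; errors on out-of-set values.
encodeLabels <- function(id, labels) {
  if (is.list(labels)) {
    vapply(labels, function(v) encodeHeadLabel(id, v), integer(1))
  } else {
    vapply(labels, function(v) encodeHeadLabel(id, v), integer(1))
  }
}

#' Train a classifier head
#'
#' The printed recipe: 1500 epochs, batch size 5, Adam, cross-entropy;
#' learning rate and weight decay 2e-4/2e-4 for head A and 1e-3/9e-5 for
#' heads B and C; early stopping monitored on validation loss with
#' best-weights restore (default patience 100 epochs). Deterministic given
#' `seed`.
#'
#' @param head An untrained head from [buildHead()].
#' @param m A [FeatureMatrix-class] of the selected features. If not yet
#'   standardized it is standardized on its own rows; the record is stored in
#'   the returned head either way.
#' @param labels Head-specific label values (one per row): priorities for A,
#'   subfield counts for B, `(MU, area)` pairs (list) for C.
#' @param seed Integer seed.
#' @param epochs,batchSize,patience Training schedule (defaults 1500/5/100).
#' @param valFraction Fraction of rows held out (stratified) for the early
#'   stopping monitor; 0 disables early stopping.
#' @return A trained [TrainedHead-class].
#' @export
trainHead <- function(head, m, labels, seed = 1, epochs = 1500, batchSize = 5,
                      patience = 100, valFraction = 0.2) {
  stopifnot(is(head, "TrainedHead"), is(m, "FeatureMatrix"))
  if (!isStandardized(m)) m <- standardizeFeatures(m)
  y <- encodeLabels(head@id, labels)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (length(y) != nrow(m@values)) stop("labels length must match feature rows")
  X <- m@values
  if (ncol(X) != head@spec$inputDim) {
    stop("head expects ", head@spec$inputDim, " features, got ", ncol(X))
  }
  fit <- withSeed(seed, {
    if (valFraction > 0) {
      folds <- stratifiedFolds(y, k = max(2L, round(1 / valFraction)), seed = seed + 1)
      valIdx <- which(folds == 1)
      trIdx <- setdiff(seq_along(y), valIdx)
      trainMLP(head@spec, X[trIdx, , drop = FALSE], y[trIdx],
        Xval = X[valIdx, , drop = FALSE], yval = y[valIdx],
        epochs = epochs, batchSize = batchSize, patience = patience
      )
    } else {
      trainMLP(head@spec, X, y,
        epochs = epochs, batchSize = batchSize,
        patience = patience
      )
    }
  })
  head@weights <- fit$weights
  head@log <- fit$log
  head@standardization <- standardizationRecord(m)
  head
}

#' Class probabilities / class predictions of a trained head
#'
#' @param head A trained [TrainedHead-class].
#' @param X Standardized feature matrix (rows = cases) or single named vector.
#' @return `predictHeadProba`: matrix of softmax probabilities (rows sum to
#'   1); `predictHeadClass`: integer class indices.
#' @export
predictHeadProba <- function(head, X) {
  stopifnot(is(head, "TrainedHead"))
  if (length(head@weights) == 0) stop("head ", head@id, " is untrained")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  mlpPredictProba(head@weights, head@spec, X)
}

#' @rdname predictHeadProba
#' @export
predictHeadClass <- function(head, X) {
  p <- predictHeadProba(head, X)
  max.col(p, ties.method = "first")
}

#' Predict Auto-FiF hyperparameters for one case
#'
#' Runs the three heads on a feature vector and decodes the argmax classes;
#' the two fixed defaults (1 open leaf pair, 0 cm leaf end separation) are
#' attached. Raw features are standardized with each head's stored training
#' record; pass `standardized = TRUE` only for already-transformed input
#' (an input that is clearly on the raw scale then raises an error).
#'
#' @param heads Named list with trained heads `A`, `B`, `C`.
#' @param v Named feature vector (selected subset).
#' @param standardized Whether `v` is already standardized.
#' @return An [AutoFifHyperparameters-class].
#' @export
predictHyperparameters <- function(heads, v, standardized = FALSE) {
  stopifnot(all(c("A", "B", "C") %in% names(heads)))
  if (standardized && max(abs(v)) > 10) {
    stop("input does not look standardized (|value| > 10); pass raw features with standardized = FALSE")
  }
  classOf <- function(head) {
    x <- v
    if (!standardized) {
      if (length(head@standardization) == 0) {
        stop("head ", head@id, " carries no standardization record; supply standardized input")
      }
      x <- applyStandardization(head@standardization, v)
    }
    predictHeadClass(head, x[seq_along(x)])
  }
  prio <- decodeHeadLabel("A", classOf(heads$A))
  nsub <- decodeHeadLabel("B", classOf(heads$B))
  combo <- decodeHeadLabel("C", classOf(heads$C))
  autoFifHyperparameters(prio, nsub, combo[1], combo[2])
}

#' Macro-averaged precision, recall and F1
#'
#' Per-class metrics averaged unweighted over the classes present in the
#' truth; classes absent from the truth are excluded with a warning. A class
#' never predicted contributes precision 0.
#'
#' @param predictions,truth Equal-length label vectors (any comparable type).
#' @return List with `perClass` data frame and scalar `precision`, `recall`,
#'   `f1`.
#' @export
macroMetrics <- function(predictions, truth) {
  if (length(predictions) != length(truth)) stop("predictions and truth differ in length")
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  classes <- sort(unique(c(predictions, truth)))
  absent <- setdiff(classes, unique(truth))
  if (length(absent) > 0) {
    warning(
      "class(es) absent from truth excluded from macro average: ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
    classes <- setdiff(classes, absent)
  }
  per <- lapply(classes, function(cl) {
    tp <- sum(predictions == cl & truth == cl)
    fp <- sum(predictions == cl & truth != cl)
    fn <- sum(predictions != cl & truth == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  list(
    perClass = per,
    precision = mean(per$precision),
    recall = mean(per$recall),
    f1 = mean(per$f1)
  )
}

#' Stratified k-fold cross-validation of a head
#'
#' Standardization is refit inside each training fold (leakage-safe); fold
#' assignment is reproducible under the seed. Classes with fewer members than
#' folds trigger a non-stratified fallback with a warning.
#'
#' @param id Head id.
#' @param m Raw (unstandardized) [FeatureMatrix-class].
#' @param labels Head-specific label values (see [trainHead()]).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param hidden Hidden-layer widths passed to [buildHead()].
#' @param ... Passed to [trainHead()] (epochs, patience, ...).
#' @return List with `perFold` (macro metrics per fold), `summary`
#'   (mean and sd of macro precision/recall/F1) and `folds`.
#' @export
crossValidateHead <- function(id, m, labels, k = 5, seed = 1, hidden = c(32, 16), ...) {
  stopifnot(is(m, "FeatureMatrix"), k >= 2)
  y <- encodeLabels(id, labels)
  counts <- table(y)
  if (any(counts < k)) {
    warning(
      "class(es) with fewer than k members; falling back to non-stratified folds",
      call. = FALSE
    )
    folds <- withSeed(seed, sample(rep_len(seq_len(k), length(y))))
  } else {
    folds <- stratifiedFolds(y, k, seed)
  }
  perFold <- vector("list", k)
  for (f in seq_len(k)) {
    trIdx <- which(folds != f)
    teIdx <- which(folds == f)
    mt <- standardizeFeatures(m, fitRows = trIdx)
    trM <- featureMatrix(mt@values[trIdx, , drop = FALSE], caseIds = m@caseIds[trIdx])
    trM@center <- mt@center
    trM@scale <- mt@scale
    trM@standardized <- TRUE
    head <- trainHead(buildHead(id, inputDim = ncol(m@values), hidden = hidden), trM,
      labels = labelSubset(labels, trIdx), seed = seed + f, ...
    )
    pred <- predictHeadClass(head, mt@values[teIdx, , drop = FALSE])
    mm <- macroMetrics(pred, y[teIdx])
    perFold[[f]] <- data.frame(
      fold = f, precision = mm$precision,
      recall = mm$recall, f1 = mm$f1
    )
  }
  perFold <- do.call(rbind, perFold)
  list(
    perFold = perFold,
    summary = data.frame(
      metric = c("precision", "recall", "f1"),
      mean = c(mean(perFold$precision), mean(perFold$recall), mean(perFold$f1)),
      sd = c(stats::sd(perFold$precision), stats::sd(perFold$recall), stats::sd(perFold$f1))
    ),
    folds = folds
  )
}

labelSubset <- function(labels, idx) {
  if (is.list(labels)) labels[idx] else labels[idx]
}

#' Save / load a trained head as a single JSON checkpoint
#'
#' The checkpoint embeds the layer spec, class decode table, weights,
#' training log and standardization record.
#'
#' @param head A [TrainedHead-class].
#' @param path Checkpoint path (`.json`).
#' @return `path` (save) or the restored [TrainedHead-class] (load).
#' @export
saveHead <- function(head, path) {
  stopifnot(is(head, "TrainedHead"))
  payload <- list(
    format = "autofif-head-v1",
    id = head@id,
    spec = head@spec,
    classes = head@classes,
    weights = lapply(head@weights, function(l) {
      list(W = as.numeric(l$W), dim = dim(l$W), b = as.numeric(l$b))
    }),
    log = head@log,
    standardization = list(
      center = as.list(head@standardization$center),
      scale = as.list(head@standardization$scale)
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveHead
#' @export
loadHead <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "autofif-head-v1")) stop("not an autofif head checkpoint: ", path)
  spec <- p$spec
  spec$inputDim <- as.integer(spec$inputDim)
  spec$hidden <- as.integer(unlist(spec$hidden))
  spec$outDim <- as.integer(spec$outDim)
  spec$activations <- as.character(unlist(spec$activations))
  spec$dropout <- as.numeric(unlist(spec$dropout))
  spec$lr <- as.numeric(spec$lr)
  spec$weightDecay <- as.numeric(spec$weightDecay)
  weights <- lapply(p$weights, function(l) {
    d <- as.integer(unlist(l$dim))
    list(W = matrix(as.numeric(unlist(l$W)), d[1], d[2]), b = as.numeric(unlist(l$b)))
  })
  classes <- lapply(p$classes, function(cl) as.numeric(unlist(cl)))
  std <- list()
  if (length(p$standardization$center) > 0) {
    std <- list(
      center = unlist(p$standardization$center),
      scale = unlist(p$standardization$scale)
    )
  }
  log <- if (length(p$log) > 0) {
    as.data.frame(lapply(
      as.data.frame(do.call(rbind, lapply(p$log, function(r) {
        unlist(lapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v)))
      }))),
      as.numeric
    ))
  } else {
    data.frame()
  }
  new("TrainedHead",
    id = p$id, spec = spec, weights = weights, classes = classes,
    log = log, standardization = std
  )
}
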