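# Classifier heads: architecture, training recipe, metrics, decoding.

test_that("head architectures have the printed class counts and settings", {
  a <- buildHead("A")
  b <- buildHead("B")
  cc <- buildHead("C")
  expect_equal(a@spec$outDim, 4)
  expect_equal(b@spec$outDim, 3)
  expect_equal(cc@spec$outDim, 4)
  expect_equal(a@spec$dropout, c(0.35, 0))
  expect_equal(b@spec$dropout, c(0.10, 0.15))
  expect_equal(a@spec$lr, 2e-4)
  expect_equal(a@spec$weightDecay, 2e-4)
  expect_equal(b@spec$lr, 1e-3)
  expect_equal(b@spec$weightDecay, 9e-5)
  # C shares B's backbone settings, with its own output dimension
  expect_equal(cc@spec$hidden, b@spec$hidden)
  expect_equal(cc@spec$dropout, b@spec$dropout)
  expect_equal(cc@spec$lr, b@spec$lr)
  expect_error(buildHead("D"), "invalid head id")
})

test_that("forward pass returns normalized probabilities, even on zeros", {
  d <- separableData()
  hd <- trainHead(buildHead("B"), d$m, d$y, seed = 1, epochs = 30, patience = 10)
  p <- predictHeadProba(hd, matrix(0, 1, 10))
  expect_length(p, 3)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  P <- predictHeadProba(hd, featureValues(d$m))
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
})

test_that("training reaches perfect accuracy on wide-margin data and is deterministic", {
  d <- separableData(n = 40, k = 2)
  hd <- trainHead(buildHead("B"), d$m, d$y, seed = 5)
  pred <- predictHeadClass(hd, featureValues(d$m))
  expect_equal(mean(pred == d$y), 1.0)

  hd2 <- trainHead(buildHead("B"), d$m, d$y, seed = 5)
  expect_identical(hd@log, hd2@log) # bit-identical loss trajectory
  expect_identical(hd@weights, hd2@weights)

  expect_error(trainHead(buildHead("B"), d$m, rep(1, 80), seed = 1), "single class")
})

test_that("randomly permuted labels train to chance-level accuracy", {
  set.seed(31)
  X <- matrix(stats::rnorm(160 * 10), 160, 10)
  colnames(X) <- paste0("f", 1:10)
  m <- standardizeFeatures(featureMatrix(X))
  y <- sample(rep(1:2, each = 80)) # labels independent of features
  tr <- 1:120
  te <- 121:160
  trM <- featureMatrix(featureValues(m)[tr, ])
  trM@center <- m@center
  trM@scale <- m@scale
  trM@standardized <- TRUE
  hd <- trainHead(buildHead("B"), trM, y[tr], seed = 3, epochs = 400, patience = 100)
  acc <- mean(predictHeadClass(hd, featureValues(m)[te, ]) == y[te])
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("macro metrics match hand-computed confusion counts", {
  # confusion [[8,2],[3,7]]: truth a: 8 a / 2 b; truth b: 3 a / 7 b
  pred <- c(rep("a", 8), rep("b", 2), rep("a", 3), rep("b", 7))
  truth <- c(rep("a", 10), rep("b", 10))
  mm <- macroMetrics(pred, truth)
  expect_equal(mm$precision, (8 / 11 + 7 / 9) / 2, tolerance = 1e-12)
  expect_equal(mm$recall, (8 / 10 + 7 / 10) / 2, tolerance = 1e-12)

  ident <- macroMetrics(truth, truth)
  expect_equal(c(ident$precision, ident$recall, ident$f1), rep(1, 3))

  # constant predictor on balanced 4-class truth: macro recall 0.25
  truth4 <- rep(c("w", "x", "y", "z"), each = 5)
  mm4 <- macroMetrics(rep("w", 20), truth4)
  expect_equal(mm4$recall, 0.25, tolerance = 1e-12)

  expect_warning(macroMetrics(c("a", "b", "q"), c("a", "b", "b")), "absent from truth")
  expect_error(macroMetrics(c("a"), c("a", "b")), "length")
})

test_that("decode/encode is the identity over all 48 label combinations", {
  for (pIdx in 1:4) {
    for (nIdx in 1:3) {
      for (cIdx in 1:4) {
        prio <- decodeHeadLabel("A", pIdx)
        nsub <- decodeHeadLabel("B", nIdx)
        combo <- decodeHeadLabel("C", cIdx)
        expect_identical(encodeHeadLabel("A", prio), pIdx)
        expect_identical(encodeHeadLabel("B", nsub), nIdx)
        expect_identical(encodeHeadLabel("C", combo), cIdx)
        h <- autoFifHyperparameters(prio, nsub, combo[1], combo[2])
        expect_equal(coveragePriority(h), c(25, 50, 75, 100)[pIdx])
        expect_equal(nSubfields(h), nIdx)
      }
    }
  }
  expect_error(encodeHeadLabel("A", 30), "not a valid class")
  expect_error(autoFifHyperparameters(30, 2, 4, 6), "coveragePriority")
})

test_that("predictHyperparameters decodes argmax classes with fixed defaults", {
  # zero-weight heads whose output bias pins the argmax
  pinned <- function(id, k) {
    hd <- buildHead(id)
    dims <- c(10, hd@spec$hidden, hd@spec$outDim)
    hd@weights <- lapply(seq_len(3), function(i) {
      list(W = matrix(0, dims[i], dims[i + 1]), b = rep(0, dims[i + 1]))
    })
    hd@weights[[3]]$b[k] <- 1
    hd@standardization <- list(center = rep(0, 10), scale = rep(1, 10))
    hd
  }
  heads <- list(A = pinned("A", 2), B = pinned("B", 3), C = pinned("C", 1))
  v <- stats::setNames(rep(0.1, 10), selectedFeatureNames())
  h <- predictHyperparameters(heads, v)
  expect_equal(coveragePriority(h), 50)
  expect_equal(nSubfields(h), 3)
  expect_equal(unname(muArea(h)), c(2, 4))
  expect_equal(h@openLeafPairs, 1)
  expect_equal(h@leafEndSeparation, 0)
  # clearly raw-scale input with standardized = TRUE is rejected
  expect_error(
    predictHyperparameters(heads, v * 200, standardized = TRUE),
    "standardized"
  )
})

test_that("cross-validation is stratified, leakage-safe and reproducible", {
  d <- separableData(n = 25, k = 3, seed = 8)
  cv1 <- crossValidateHead("B", featureMatrix(4 + 2 * featureValues(d$m)), d$y,
    k = 5, seed = 4, epochs = 120, patience = 40
  )
  cv2 <- crossValidateHead("B", featureMatrix(4 + 2 * featureValues(d$m)), d$y,
    k = 5, seed = 4, epochs = 120, patience = 40
  )
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$perFold, cv2$perFold)
  expect_equal(cv1$summary$mean[cv1$summary$metric == "f1"], 1.0)
  # every fold holds one fifth of each class
  for (f in 1:5) expect_equal(as.integer(table(d$y[cv1$folds == f])), rep(5L, 3))

  expect_warning(
    crossValidateHead("B", d$m, c(rep(1, 72), rep(2, 3)),
      k = 5, seed = 1,
      epochs = 20, patience = 10
    ),
    "non-stratified"
  )
})

test_that("head checkpoints round-trip through JSON", {
  d <- separableData(n = 30, k = 4, seed = 12)
  hd <- trainHead(buildHead("C"), d$m, lapply(d$y, function(k) decodeHeadLabel("C", k)),
    seed = 2, epochs = 150, patience = 50
  )
  f <- file.path(tempdir(), "head_C.json")
  saveHead(hd, f)
  hd2 <- loadHead(f)
  expect_equal(hd2@weights, hd@weights, tolerance = 1e-12)
  expect_identical(hd2@id, hd@id)
  expect_equal(hd2@classes, hd@classes)
  expect_equal(hd2@standardization$center, hd@standardization$center, tolerance = 1e-12)
  X <- featureValues(d$m)
  expect_identical(predictHeadClass(hd2, X), predictHeadClass(hd, X))
  junk <- file.path(tempdir(), "junk.json")
  jsonlite::write_json(list(format = "other"), junk, auto_unbox = TRUE)
  expect_error(loadHead(junk), "checkpoint")
})
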