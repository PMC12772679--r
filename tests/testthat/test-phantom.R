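# Synthetic anatomy generator and labeled datasets.

test_that("zero jitter gives an exactly mirror-symmetric phantom", {
  s <- generatePhantom(phantomSpec(asymmetryJitter = 0))
  eL <- structurePoints(s, "EYE_L")
  eR <- structurePoints(s, "EYE_R")
  expect_equal(unname(eR), unname(cbind(-eL[, 1], eL[, 2], eL[, 3])), tolerance = 0)
  expect_equal(organVolume(eL), organVolume(eR), tolerance = 1e-12)
  expect_equal(organDiameter(eL), organDiameter(eR), tolerance = 1e-12)
  lL <- structurePoints(s, "LENS_L")
  expect_lt(mean(lL[, 2]), mean(eL[, 2])) # lens anterior to eye center
  expect_lt(organDiameter(lL), organDiameter(eL))
})

test_that("phantom generation is deterministic under the spec seed", {
  a <- generatePhantom(randomPhantomSpec(77))
  b <- generatePhantom(randomPhantomSpec(77))
  expect_identical(structures(a), structures(b))
  expect_identical(isocenter(a), isocenter(b))
  c2 <- generatePhantom(randomPhantomSpec(78))
  expect_false(identical(structures(a), structures(c2)))
})

test_that("default spec ranges put the brain Feret diameter in 14-19 cm", {
  diams <- vapply(1:100, function(i) {
    organDiameter(structurePoints(generatePhantom(randomPhantomSpec(i)), "BRAIN_CTV"))
  }, numeric(1))
  expect_true(all(diams >= 14 & diams <= 19))
  expect_gt(max(diams) - min(diams), 2) # the range is actually exercised
})

test_that("every generated case passes structure invariants and yields 21 finite features", {
  for (i in c(201, 202, 203)) {
    s <- generatePhantom(randomPhantomSpec(i))
    expect_true(validObject(s))
    v <- extractFeatures(s)
    expect_length(v, 21)
    expect_true(all(is.finite(v)))
  }
})

test_that("noise-free labels are reproduced by re-applying the rule", {
  ds <- cached("ds60", generateLabeledDataset(60, noise = 0, seed = 19))
  for (cs in ds) {
    h2 <- labelRule(cs$features)
    expect_equal(coveragePriority(cs$hyperparameters), coveragePriority(h2))
    expect_equal(nSubfields(cs$hyperparameters), nSubfields(h2))
    expect_equal(muArea(cs$hyperparameters), muArea(h2))
  }
  # all classes of every head occupied
  cb <- attr(ds, "classBalance")
  expect_length(cb$coveragePriority, 4)
  expect_length(cb$nSubfields, 3)
  expect_length(cb$muArea, 4)
  # determinism
  ds2 <- generateLabeledDataset(60, noise = 0, seed = 19)
  expect_equal(
    vapply(ds, function(cs) coveragePriority(cs$hyperparameters), numeric(1)),
    vapply(ds2, function(cs) coveragePriority(cs$hyperparameters), numeric(1))
  )
})

test_that("label flipping hits the requested rate", {
  ds <- generateLabeledDataset(200, noise = 0.1, seed = 23)
  flips <- 0
  for (cs in ds) {
    clean <- labelRule(cs$features)
    flips <- flips +
      (coveragePriority(cs$hyperparameters) != coveragePriority(clean)) +
      (nSubfields(cs$hyperparameters) != nSubfields(clean)) +
      sum(any(muArea(cs$hyperparameters) != muArea(clean)))
  }
  rate <- flips / (3 * length(ds)) # 600 labels
  expect_lt(abs(rate - 0.1), 0.03)
  expect_error(generateLabeledDataset(10, noise = 0.7), "noise")
})

test_that("closed-loop label draws are uniform over the restricted combos", {
  stub <- tpsAdapter("stub", function(s, h, prescription, seed) {
    fakePlan(brain = rep(prescription, 10))
  })
  cl <- generateClosedLoopDataset(480, stub, seed = 41)
  labels <- vapply(cl, function(cs) {
    paste(
      coveragePriority(cs$hyperparameters), nSubfields(cs$hyperparameters),
      paste(muArea(cs$hyperparameters), collapse = ","),
      sep = "|"
    )
  }, character(1))
  counts <- table(labels)
  expect_equal(length(counts), 48)
  chi <- stats::chisq.test(as.numeric(counts), p = rep(1 / 48, 48))
  expect_gt(chi$p.value, 0.01)
  # determinism
  cl2 <- generateClosedLoopDataset(5, stub, seed = 41)
  expect_identical(
    structures(cl2[[1]]$structureSet),
    structures(cl[[1]]$structureSet)
  )
})

test_that("dataset fixtures round-trip through the plain-text export", {
  ds <- cached("ds60", generateLabeledDataset(60, noise = 0, seed = 19))[1:4]
  dir <- file.path(tempdir(), "fixtures")
  saveDatasetFixtures(ds, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  back <- loadLabeledDataset(dir)
  expect_length(back, 4)
  for (i in 1:4) {
    expect_equal(structures(back[[i]]$structureSet), structures(ds[[i]]$structureSet))
    expect_equal(
      coveragePriority(back[[i]]$hyperparameters),
      coveragePriority(ds[[i]]$hyperparameters)
    )
    expect_equal(back[[i]]$features, ds[[i]]$features, tolerance = 1e-9)
  }
})
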