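# DVH metrics, D95 normalization and paired plan comparison.

test_that("Dx% is exact on uniform and two-voxel structures", {
  p <- fakePlan(brain = rep(30, 200))
  expect_equal(doseAtVolume(p, "BRAIN_CTV", 1), 30)
  expect_equal(doseAtVolume(p, "BRAIN_CTV", 95), 30)
  expect_equal(doseAtVolume(p, "BRAIN_CTV", 99), 30)

  p2 <- fakePlan(brain = c(10, 20))
  expect_lte(doseAtVolume(p2, "BRAIN_CTV", 95), 10)
  expect_gt(doseAtVolume(p2, "BRAIN_CTV", 1), 10)
  expect_error(doseAtVolume(p2, "BRAIN_CTV", 0), "strictly between")
  expect_error(doseAtVolume(p2, "BRAIN_CTV", 100), "strictly between")
})

test_that("Dx% and mean dose equal brute-force sort-based oracles to 1e-9", {
  set.seed(12)
  doses <- stats::rgamma(1000, shape = 20, rate = 0.7)
  p <- fakePlan(brain = doses)
  for (x in c(1, 5, 50, 95, 99)) {
    expect_equal(doseAtVolume(p, "BRAIN_CTV", x), oracleDx(doses, x), tolerance = 1e-9)
  }
  expect_equal(meanDose(p, "BRAIN_CTV"), sum(doses) / length(doses), tolerance = 1e-9)
  expect_equal(meanDose(fakePlan(brain = 1, eye = c(0, 10)), "EYE_L"), 5)
})

test_that("D95 normalization is exact, linear and idempotent", {
  set.seed(13)
  doses <- stats::runif(800, 20, 35)
  p <- fakePlan(brain = doses)
  d95 <- doseAtVolume(p, "BRAIN_CTV", 95)
  # the worked case: 28.5 -> 30.0
  pScaled <- fakePlan(brain = doses * 28.5 / d95)
  pn <- normalizeToD95(pScaled, 30.0)
  expect_equal(doseAtVolume(pn, "BRAIN_CTV", 95), 30.0, tolerance = 1e-9)
  # all other Dx% scale by the same factor
  f <- 30.0 / 28.5
  for (x in c(1, 50, 99)) {
    expect_equal(doseAtVolume(pn, "BRAIN_CTV", x),
      doseAtVolume(pScaled, "BRAIN_CTV", x) * f,
      tolerance = 1e-9
    )
  }
  expect_equal(meanDose(pn, "EYE_L"), meanDose(pScaled, "EYE_L") * f, tolerance = 1e-9)
  # identity and idempotence
  pSame <- normalizeToD95(p, d95)
  expect_equal(structureDose(pSame), structureDose(p), tolerance = 1e-12)
  pTwice <- normalizeToD95(pn, 30.0)
  expect_equal(structureDose(pTwice), structureDose(pn), tolerance = 1e-12)
  expect_error(normalizeToD95(fakePlan(brain = rep(0, 10)), 30), "zero")
})

test_that("paired comparison matches the closed-form t-test and guards degeneracy", {
  mk <- function(d95) {
    m <- dvhMetrics(fakePlan(brain = seq(25, 35, length.out = 50) * d95 / 30))
    m
  }
  a <- lapply(c(29, 30, 31, 30.5, 29.5), mk)
  b <- lapply(c(29.2, 30.1, 30.8, 30.9, 29.1), mk)
  cmp <- comparePlans(a, b)
  # closed-form paired t on one metric
  av <- vapply(a, function(m) m[["D95_BRAIN_CTV"]], numeric(1))
  bv <- vapply(b, function(m) m[["D95_BRAIN_CTV"]], numeric(1))
  d <- av - bv
  tRef <- mean(d) / (stats::sd(d) / sqrt(5))
  pRef <- 2 * stats::pt(-abs(tRef), df = 4)
  row <- cmp[cmp$metric == "D95_BRAIN_CTV", ]
  expect_equal(row$t, tRef, tolerance = 1e-9)
  expect_equal(row$p, pRef, tolerance = 1e-9)

  # identical cohorts: degenerate, p = 1, never "significant"
  cmpSame <- comparePlans(a, a)
  expect_true(all(cmpSame$degenerate))
  expect_true(all(cmpSame$p == 1))
  expect_false(any(cmpSame$significant))

  # constant +1 shift: zero-variance differences flagged degenerate, not NaN
  aShift <- lapply(a, function(m) m + 1)
  cmpShift <- comparePlans(aShift, a)
  expect_true(all(cmpShift$degenerate))
  expect_true(all(is.finite(cmpShift$p)))

  expect_error(comparePlans(a, b[1:3]), "length")
  expect_error(comparePlans(a[1], b[1]), "at least 2")
})
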