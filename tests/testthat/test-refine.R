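# Staged localized re-search with revert fallback.

countingEngine <- function() {
  env <- new.env()
  env$n <- 0
  base <- surrogateEngine()
  eng <- tpsAdapter(
    "counting",
    generatePlan = function(s, h, prescription, seed) {
      env$n <- env$n + 1
      base$generatePlan(s, h, prescription, seed)
    },
    newContext = base$newContext,
    planFromContext = function(ctx, h, prescription) {
      env$n <- env$n + 1
      base$planFromContext(ctx, h, prescription)
    }
  )
  list(engine = eng, calls = function() env$n)
}

refineFixture <- function() {
  cached("refineFixture", {
    s <- generatePhantom(randomPhantomSpec(31))
    h0 <- autoFifHyperparameters(50, 2, 4, 6)
    plan0 <- generatePlan(s, h0, 30, seed = 4)
    list(s = s, h0 = h0, plan0 = plan0, m0 = dvhMetrics(plan0))
  })
}

test_that("a stage-1-satisfiable coverage critique raises only the priority", {
  fx <- refineFixture()
  fb <- interpretFeedback("The target coverage is poor")
  obj <- feedbackToObjective(fb, fx$m0)
  ce <- countingEngine()
  res <- refinePlan(fx$s, fx$h0, fx$plan0, obj, ce$engine)
  expect_equal(res$outcome, "refined")
  expect_equal(res$stage, 1L)
  expect_equal(coveragePriority(res$hyperparameters), 75) # 50 -> 75
  expect_equal(nSubfields(res$hyperparameters), nSubfields(fx$h0)) # untouched
  expect_equal(muArea(res$hyperparameters), muArea(fx$h0))
  m1 <- dvhMetrics(res$plan)
  # accepted coverage refinements honor the >= 5% improvement rule
  expect_true(m1[["D95_BRAIN_CTV"]] >= 1.05 * fx$m0[["D95_BRAIN_CTV"]] - 1e-9 ||
    m1[["D99_BRAIN_CTV"]] >= 1.05 * fx$m0[["D99_BRAIN_CTV"]] - 1e-9)
  # guards: unnamed metrics within 2%
  for (k in c("Mean_EYE_L", "Mean_EYE_R", "Mean_LENS_L", "Mean_LENS_R", "D1_BRAIN_CTV")) {
    expect_lte(m1[[k]], fx$m0[[k]] * 1.02 + 1e-9)
  }
  expect_lte(ce$calls(), 4) # stage 1 evaluates at most 4 configurations
})

test_that("an OAR critique unsatisfiable in stage 1 adds a subfield in stage 2", {
  fx <- refineFixture()
  fb <- interpretFeedback(paste0(
    "The mean doses to the right and left eyes look a bit too high — ",
    "I’d suggest lowering them. Target coverage seems fine."
  ))
  obj <- feedbackToObjective(fb, fx$m0)
  ce <- countingEngine()
  res <- refinePlan(fx$s, fx$h0, fx$plan0, obj, ce$engine)
  expect_equal(res$outcome, "refined")
  expect_equal(res$stage, 2L)
  expect_equal(nSubfields(res$hyperparameters), 3) # 2 -> 3
  expect_equal(coveragePriority(res$hyperparameters), 50) # unchanged
  m1 <- dvhMetrics(res$plan)
  expect_lte(m1[["Mean_EYE_R"]], 0.95 * fx$m0[["Mean_EYE_R"]] + 1e-9)
  expect_lte(m1[["Mean_EYE_L"]], 0.95 * fx$m0[["Mean_EYE_L"]] + 1e-9)
  # coverage guard: D95 not lower by more than 2%
  expect_gte(m1[["D95_BRAIN_CTV"]], 0.98 * fx$m0[["D95_BRAIN_CTV"]] - 1e-9)
  # stage 1 configs were tried (and logged) before stage 2
  expect_true(any(res$log$stage == 1))
  expect_lte(ce$calls(), 16) # <= 4 + <= 12 per feedback round
})

test_that("an impossible objective reverts to the initial plan bit-exactly", {
  fx <- refineFixture()
  s <- fx$s
  h100 <- autoFifHyperparameters(100, 2, 4, 6)
  p100 <- generatePlan(s, h100, 30, seed = 4)
  fb <- interpretFeedback("The target coverage is poor")
  obj <- feedbackToObjective(fb, dvhMetrics(p100))
  res <- refinePlan(s, h100, p100, obj)
  expect_equal(res$outcome, "reverted")
  expect_identical(res$plan, p100)
  expect_identical(res$hyperparameters, h100)
  expect_true(all(!res$log$accepted))
})

test_that("the decision log records every configuration with metrics and verdicts", {
  fx <- refineFixture()
  fb <- interpretFeedback("The target coverage is poor")
  obj <- feedbackToObjective(fb, fx$m0)
  res <- refinePlan(fx$s, fx$h0, fx$plan0, obj)
  expect_true(all(c(
    "stage", "coveragePriority", "nSubfields",
    "D95_BRAIN_CTV", "goalsMet", "guardsOk", "accepted"
  ) %in% names(res$log)))
  expect_equal(sum(res$log$accepted), 1)
  expect_equal(res$log$coveragePriority[nrow(res$log)], 75)
})
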