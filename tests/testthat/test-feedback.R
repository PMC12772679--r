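# Conversation module: interpretation, objectives, transcription.

test_that("the rule-based interpreter maps the canonical critiques", {
  f1 <- interpretFeedback("The target coverage is poor")
  expect_equal(f1@targetCoverage, "bad")
  expect_equal(f1@oarDose, "unchanged")

  f2 <- interpretFeedback(paste0(
    "The target coverage doesn’t look great — I’d definitely ",
    "want to improve that part. The rest seems alright."
  ))
  expect_equal(f2@targetCoverage, "bad")
  expect_equal(f2@oarDose, "unchanged")

  f3 <- interpretFeedback(paste0(
    "The mean doses to the right and left eyes look a bit too high — ",
    "I’d suggest lowering them. Target coverage seems fine."
  ))
  expect_equal(f3@targetCoverage, "good")
  expect_equal(f3@oarDose, "high")
  expect_setequal(f3@oarRoles, c("EYE_L", "EYE_R"))

  f4 <- interpretFeedback("Everything looks fine, nothing to change.")
  expect_false(isActionable(f4))

  f5 <- interpretFeedback("Please reduce the dose to the left lens.")
  expect_equal(f5@oarDose, "high")
  expect_identical(f5@oarRoles, "LENS_L")

  # determinism
  expect_identical(
    interpretFeedback("The target coverage is poor"),
    interpretFeedback("The target coverage is poor")
  )
  expect_error(interpretFeedback("   "), "non-empty")
})

test_that("schema-invalid interpreter output is retried once, then errors", {
  calls <- 0
  flaky <- function(transcript) {
    calls <<- calls + 1
    if (calls == 1) list(bogus = TRUE) else list(target_coverage = "bad", oar_dose = "unchanged")
  }
  fb <- interpretFeedback("coverage is poor", flaky)
  expect_equal(calls, 2)
  expect_equal(fb@targetCoverage, "bad")

  alwaysBad <- function(transcript) list(bogus = TRUE)
  expect_error(interpretFeedback("x", alwaysBad), "schema-invalid output twice")
})

test_that("the LLM backend wrapper replays recorded responses and accepts the paper key spellings", {
  recorded <- function(prompt, temperature) {
    expect_equal(temperature, 0.2)
    expect_match(prompt, "Feedback: The target coverage is poor")
    '{"target coverage": "bad", "OAR_dose": "unchanged"}'
  }
  fb <- interpretFeedback("The target coverage is poor", llmInterpreter(recorded))
  expect_equal(fb@targetCoverage, "bad")
  expect_equal(fb@oarDose, "unchanged")
  expect_equal(fb@interpreter, "llm")
})

test_that("feedback maps to the 5% objective with the printed worked values", {
  initial <- c(
    D1_BRAIN_CTV = 32, D95_BRAIN_CTV = 28.5, D99_BRAIN_CTV = 27,
    Mean_EYE_L = 19.6, Mean_EYE_R = 23.3, Mean_LENS_L = 8.4, Mean_LENS_R = 6.1
  )
  fb <- interpretFeedback("The target coverage is poor")
  obj <- feedbackToObjective(fb, initial)
  expect_equal(obj$coverage$minD95, 29.925, tolerance = 1e-12) # 1.05 * 28.5
  expect_equal(obj$coverage$minD99, 1.05 * 27, tolerance = 1e-12)
  expect_length(obj$oarLimits, 0)

  fbEyes <- interpretFeedback("The doses to the right and left eyes are too high.")
  obj2 <- feedbackToObjective(fbEyes, initial)
  expect_equal(unname(obj2$oarLimits["Mean_EYE_R"]), 22.135, tolerance = 1e-12) # 0.95 * 23.3
  expect_equal(unname(obj2$oarLimits["Mean_EYE_L"]), 18.62, tolerance = 1e-12) # 0.95 * 19.6
  expect_null(obj2$coverage)

  fbNone <- interpretFeedback("all good here, coverage is fine")
  expect_error(feedbackToObjective(fbNone, initial), "not actionable")
  expect_error(feedbackToObjective(fb, initial, coverageGain = 0), "positive")
})

test_that("transcription dispatches to the backend with a clear no-backend error", {
  expect_identical(transcribe("hello plan"), "hello plan")
  expect_error(transcribe(""), "non-empty")
  expect_error(transcribe("x", backend = NULL), "provide the feedback as text")
  upper <- function(a) toupper(a)
  expect_identical(transcribe("ok", upper), "OK")
})
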