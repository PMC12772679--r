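# Conversation loop: transcript -> structured feedback -> quantitative
# objective -> staged localized hyperparameter re-search with revert
# fallback.

.COVERAGE_TERMS <- "coverage|target"
.OAR_TERMS <- "\\beyes?\\b|\\blens(es)?\\b|\\boars?\\b"
.NEGATIVE_TERMS <- paste0(
  "\\bpoor\\b|\\bbad\\b|insufficient|inadequate|suboptimal|lacking|",
  "not (very )?good|not great|n['\u2019]t (look|seem)s? (great|good|fine|right)|",
  "improve|boost|too low|\\blow\\b|under-?cover"
)
.POSITIVE_TERMS <- "\\bfine\\b|\\bgood\\b|\\bgreat\\b|adequate|acceptable|alright|\\bokay?\\b|satisf|no (issues|concerns)"
.HIGH_DOSE_TERMS <- "too high|\\bhigh\\b|\\bhot\\b|elevated|excessive|lower(ing)?\\b|reduce|decrease|bring .*down|spar(e|ing)"
.NEGATION <- "\\bnot\\b|n['\u2019]t\\b|\\bno\\b|\\bnever\\b"

splitSentences <- function(text) {
  s <- unlist(strsplit(text, "[.!?;]+"))
  s <- trimws(s)
  tolower(s[nzchar(s)])
}

oarRolesInSentence <- function(sentence) {
  roles <- character(0)
  hasRight <- grepl("\\bright\\b|\\brt\\b|_r\\b", sentence)
  hasLeft <- grepl("\\bleft\\b|\\blt\\b|_l\\b", sentence)
  if (grepl("\\beyes?\\b", sentence)) {
    if (hasRight) roles <- c(roles, "EYE_R")
    if (hasLeft) roles <- c(roles, "EYE_L")
    if (!hasRight && !hasLeft) roles <- c(roles, "EYE_L", "EYE_R")
  }
  if (grepl("\\blens(es)?\\b", sentence)) {
    if (hasRight) roles <- c(roles, "LENS_R")
    if (hasLeft) roles <- c(roles, "LENS_L")
    if (!hasRight && !hasLeft) roles <- c(roles, "LENS_L", "LENS_R")
  }
  unique(roles)
}

#' Deterministic rule-based feedback interpreter
#'
#' Sentence-level keyword mapping: sentences naming the target/coverage are
#' scored for negative ("poor", "doesn't look great", "improve", ...) versus
#' positive sentiment; sentences naming OARs (eyes/lenses) are scored for
#' elevated-dose language ("too high", "lowering", ...), with left/right
#' qualifiers resolved to roles. Deterministic: identical transcript,
#' identical feedback. This is the default backend in offline use and in
#' tests.
#'
#' @return An interpreter backend: `function(transcript) -> list` with keys
#'   `target_coverage`, `oar_dose`, `oar_roles`.
#' @export
rulesInterpreter <- function() {
  backend <- function(transcript) {
    sentences <- splitSentences(transcript)
    coverage <- "unchanged"
    oar <- "unchanged"
    oarRoles <- character(0)
    for (sn in sentences) {
      if (grepl(.COVERAGE_TERMS, sn)) {
        neg <- grepl(.NEGATIVE_TERMS, sn, perl = TRUE)
        pos <- grepl(.POSITIVE_TERMS, sn) && !grepl(.NEGATION, sn, perl = TRUE)
        if (neg) {
          coverage <- "bad"
        } else if (pos && !identical(coverage, "bad")) {
          coverage <- "good"
        }
      }
      if (grepl(.OAR_TERMS, sn, perl = TRUE)) {
        high <- grepl(.HIGH_DOSE_TERMS, sn, perl = TRUE)
        pos <- grepl(.POSITIVE_TERMS, sn) && !grepl(.NEGATION, sn, perl = TRUE)
        if (high) {
          oar <- "high"
          oarRoles <- unique(c(oarRoles, oarRolesInSentence(sn)))
        } else if (pos && !identical(oar, "high")) {
          oar <- "good"
        }
      }
    }
    list(target_coverage = coverage, oar_dose = oar, oar_roles = oarRoles)
  }
  attr(backend, "interpreterId") <- "rules"
  backend
}

#' LLM-backed feedback interpreter
#'
#' Wraps an arbitrary chat-completion callback behind the interpreter
#' interface. The callback receives a prompt built from the shipped few-shot
#' exemplars (`inst/extdata/feedback_exemplars.json`) plus the transcript and
#' must return the model's raw text; the JSON payload is extracted and
#' schema-validated by [interpretFeedback()]. A low sampling temperature
#' (default 0.2) is passed through for reproducible outputs. For offline
#' tests, supply a recorded-response callback.
#'
#' @param responder `function(prompt, temperature) -> character` (raw model
#'   output).
#' @param temperature Sampling temperature forwarded to the responder.
#' @param exemplarsPath Path to a few-shot exemplar JSON file.
#' @return An interpreter backend for [interpretFeedback()].
#' @export
llmInterpreter <- function(responder, temperature = 0.2,
                           exemplarsPath = system.file("extdata", "feedback_exemplars.json",
                             package = "autofif"
                           )) {
  stopifnot(is.function(responder))
  exemplars <- jsonlite::read_json(exemplarsPath, simplifyVector = FALSE)
  shots <- vapply(exemplars, function(ex) {
    paste0(
      "Feedback: ", ex$input, "\nJSON: ",
      jsonlite::toJSON(ex$output, auto_unbox = TRUE)
    )
  }, character(1))
  backend <- function(transcript) {
    prompt <- paste0(
      "Convert physician feedback about a whole-brain radiotherapy plan into JSON with keys ",
      "\"target_coverage\" (good|bad|unchanged), \"oar_dose\" (good|high|unchanged) and ",
      "\"oar_roles\" (subset of EYE_L, EYE_R, LENS_L, LENS_R).\n\n",
      paste(shots, collapse = "\n\n"),
      "\n\nFeedback: ", transcript, "\nJSON:"
    )
    raw <- responder(prompt, temperature)
    m <- regmatches(raw, regexpr("\\{[^{}]*\\}", raw))
    if (length(m) == 0) stop("no JSON object in interpreter output: ", raw)
    jsonlite::fromJSON(m, simplifyVector = FALSE)
  }
  attr(backend, "interpreterId") <- "llm"
  backend
}

# Normalize and validate a backend payload against the feedback schema.
# Accepts both spaced and snake_case key spellings.
validateFeedbackPayload <- function(payload) {
  if (!is.list(payload)) stop("feedback payload is not a JSON object")
  names(payload) <- tolower(gsub("[ -]", "_", names(payload)))
  coverage <- payload[["target_coverage"]]
  oar <- payload[["oar_dose"]]
  if (is.null(coverage) || is.null(oar)) {
    stop("feedback payload lacks target_coverage/oar_dose keys")
  }
  coverage <- tolower(as.character(coverage))
  oar <- tolower(as.character(oar))
  if (!coverage %in% c("good", "bad", "unchanged")) {
    stop("invalid target_coverage value: ", coverage)
  }
  if (!oar %in% c("good", "high", "unchanged")) {
    stop("invalid oar_dose value: ", oar)
  }
  roles <- toupper(unlist(payload[["oar_roles"]]))
  if (length(roles) > 0 && !all(roles %in% .oarRoles())) {
    stop("invalid oar_roles: ", paste(setdiff(roles, .oarRoles()), collapse = ", "))
  }
  list(targetCoverage = coverage, oarDose = oar, oarRoles = as.character(roles))
}

#' Interpret a plan critique into structured feedback
#'
#' Runs the backend on the transcript and validates its output against the
#' feedback schema (one retry on schema-invalid output, then an error
#' carrying the raw payload).
#'
#' @param transcript Non-empty critique text.
#' @param backend Interpreter backend (default [rulesInterpreter()]).
#' @return A [StructuredFeedback-class].
#' @export
interpretFeedback <- function(transcript, backend = rulesInterpreter()) {
  if (!is.character(transcript) || !nzchar(trimws(transcript))) {
    stop("transcript must be non-empty text")
  }
  parsed <- tryCatch(
    validateFeedbackPayload(backend(transcript)),
    error = function(firstErr) {
      tryCatch(
        validateFeedbackPayload(backend(transcript)),
        error = function(e) {
          stop(
            "interpreter produced schema-invalid output twice: ",
            conditionMessage(e),
            call. = FALSE
          )
        }
      )
    }
  )
  new("StructuredFeedback",
    targetCoverage = parsed$targetCoverage,
    oarDose = parsed$oarDose,
    oarRoles = parsed$oarRoles,
    transcript = transcript,
    interpreter = if (!is.null(attr(backend, "interpreterId"))) attr(backend, "interpreterId") else "custom"
  )
}

#' Translate structured feedback into a refinement objective
#'
#' Coverage judged bad becomes: raise D95% or D99% by at least
#' `coverageGain` (default 5%) relative to the initial plan. OAR dose judged
#' high becomes: lower each named OAR's mean dose by at least `oarDrop`
#' (default 5%, mirroring the coverage threshold). Metrics not named by any
#' goal are protected by a guard: they may not worsen by more than
#' `guardTolerance` (default 2%) relative.
#'
#' @param f An actionable [StructuredFeedback-class].
#' @param initial [dvhMetrics()] vector of the initial plan.
#' @param coverageGain,oarDrop,guardTolerance Relative thresholds (> 0).
#' @return A `RefinementObjective` (classed list).
#' @export
feedbackToObjective <- function(f, initial, coverageGain = 0.05, oarDrop = 0.05,
                                guardTolerance = 0.02) {
  stopifnot(is(f, "StructuredFeedback"))
  if (coverageGain <= 0 || oarDrop <= 0 || guardTolerance <= 0) {
    stop("thresholds must be positive")
  }
  if (!isActionable(f)) {
    stop("feedback is not actionable (no coverage or OAR goal)")
  }
  coverage <- NULL
  oarLimits <- numeric(0)
  if (identical(f@targetCoverage, "bad")) {
    coverage <- list(
      minD95 = (1 + coverageGain) * initial[["D95_BRAIN_CTV"]],
      minD99 = (1 + coverageGain) * initial[["D99_BRAIN_CTV"]]
    )
  }
  if (identical(f@oarDose, "high")) {
    roles <- if (length(f@oarRoles) > 0) f@oarRoles else .oarRoles()
    oarLimits <- stats::setNames(
      (1 - oarDrop) * initial[paste0("Mean_", roles)],
      paste0("Mean_", roles)
    )
  }
  structure(
    list(
      coverage = coverage, oarLimits = oarLimits,
      guardTolerance = guardTolerance, initial = initial
    ),
    class = "RefinementObjective"
  )
}

# Goal-named metric keys of an objective.
objectiveNamedMetrics <- function(obj) {
  keys <- character(0)
  if (!is.null(obj$coverage)) keys <- c(keys, "D95_BRAIN_CTV", "D99_BRAIN_CTV")
  keys <- c(keys, names(obj$oarLimits))
  keys
}

.LOWER_WORSE <- c("D95_BRAIN_CTV", "D99_BRAIN_CTV")

objectiveSatisfied <- function(obj, metrics) {
  eps <- 1e-9
  if (!is.null(obj$coverage)) {
    coverageOk <- metrics[["D95_BRAIN_CTV"]] >= obj$coverage$minD95 - eps ||
      metrics[["D99_BRAIN_CTV"]] >= obj$coverage$minD99 - eps
    if (!coverageOk) {
      return(FALSE)
    }
  }
  if (length(obj$oarLimits) > 0) {
    if (any(metrics[names(obj$oarLimits)] > obj$oarLimits + eps)) {
      return(FALSE)
    }
  }
  TRUE
}

guardsSatisfied <- function(obj, metrics) {
  eps <- 1e-9
  tol <- obj$guardTolerance
  guarded <- setdiff(names(obj$initial), objectiveNamedMetrics(obj))
  for (k in guarded) {
    init <- obj$initial[[k]]
    val <- metrics[[k]]
    ok <- if (k %in% .LOWER_WORSE) {
      val >= init * (1 - tol) - eps
    } else {
      val <= init * (1 + tol) + eps
    }
    if (!ok) {
      return(FALSE)
    }
  }
  TRUE
}

.PRIORITY_LEVELS <- c(25, 50, 75, 100)

#' Staged localized hyperparameter re-search
#'
#' Stage 1 varies coverage priority only, holding all other settings at the
#' initial values; stage 2, entered only if stage 1 finds no satisfactory
#' configuration, varies coverage priority and the number of subfields
#' jointly. A configuration is satisfactory when every active goal is met
#' and no guarded metric worsens beyond the tolerance. If neither stage
#' succeeds the initial plan is returned unchanged (outcome `"reverted"`).
#'
#' Search order is deterministic and prefers the smallest perturbation:
#' coverage goals walk the priority ladder upward from the initial value;
#' OAR goals prefer adding subfields, then lowering priority. The first
#' satisfactory configuration wins. Stage 1 evaluates at most 3
#' configurations and stage 2 at most 11.
#'
#' @param s The case's [StructureSet-class].
#' @param initialH Initial [AutoFifHyperparameters-class] (from prediction).
#' @param initialPlan The initial [PlanResult-class].
#' @param objective A [feedbackToObjective()] result.
#' @param engine A [tpsAdapter()] (default [surrogateEngine()]).
#' @param prescription,seed Plan-generation settings (defaults: the initial
#'   plan's).
#' @return List with `outcome` (`"refined"` or `"reverted"`), `plan`,
#'   `hyperparameters`, `stage` (1, 2 or NA) and `log` (one row per tried
#'   configuration with metric values and verdicts).
#' @export
refinePlan <- function(s, initialH, initialPlan, objective,
                       engine = surrogateEngine(),
                       prescription = initialPlan@prescription,
                       seed = initialPlan@seed) {
  stopifnot(
    is(initialH, "AutoFifHyperparameters"), is(initialPlan, "PlanResult"),
    inherits(objective, "RefinementObjective")
  )
  coverageGoal <- !is.null(objective$coverage)
  ctx <- NULL
  if (!is.null(engine$newContext) && !is.null(engine$planFromContext)) {
    ctx <- engine$newContext(s, seed = seed)
  }
  makePlan <- function(h) {
    if (!is.null(ctx)) {
      engine$planFromContext(ctx, h, prescription)
    } else {
      engine$generatePlan(s, h, prescription, seed)
    }
  }
  p0 <- initialH@coveragePriority
  n0 <- initialH@nSubfields
  p0i <- match(p0, .PRIORITY_LEVELS)
  n0i <- n0

  logRows <- list()
  tryConfig <- function(stage, priority, nsub) {
    h <- autoFifHyperparameters(priority, nsub, initialH@minSegmentMU, initialH@minSegmentArea)
    plan <- tryCatch(makePlan(h), error = function(e) {
      warning("engine failed at priority ", priority, ", subfields ", nsub,
        "; skipped (", conditionMessage(e), ")",
        call. = FALSE
      )
      NULL
    })
    if (is.null(plan)) {
      return(NULL)
    }
    m <- dvhMetrics(plan)
    goals <- objectiveSatisfied(objective, m)
    guards <- guardsSatisfied(objective, m)
    logRows[[length(logRows) + 1]] <<- data.frame(
      stage = stage, coveragePriority = priority, nSubfields = nsub,
      t(m), goalsMet = goals, guardsOk = guards, accepted = goals && guards
    )
    if (goals && guards) list(plan = plan, h = h) else NULL
  }

  # stage 1: coverage priority only
  stage1 <- if (coverageGoal) {
    .PRIORITY_LEVELS[.PRIORITY_LEVELS > p0]
  } else {
    rev(.PRIORITY_LEVELS[.PRIORITY_LEVELS < p0])
  }
  for (pr in stage1) {
    hit <- tryConfig(1L, pr, n0)
    if (!is.null(hit)) {
      return(list(
        outcome = "refined", plan = hit$plan, hyperparameters = hit$h,
        stage = 1L, log = do.call(rbind, logRows)
      ))
    }
  }

  # stage 2: (priority, subfields) jointly, smallest perturbation first
  cand <- expand.grid(pi = seq_along(.PRIORITY_LEVELS), ni = c(1, 2, 3))
  cand <- cand[!(cand$pi == p0i & cand$ni == n0i), ]
  dist <- abs(cand$pi - p0i) + abs(cand$ni - n0i)
  if (coverageGoal) {
    pref1 <- ifelse(cand$pi > p0i, 0, 1) # priority increases first
    pref2 <- abs(cand$ni - n0i)
    pref3 <- -cand$pi
  } else {
    pref1 <- ifelse(cand$ni > n0i, 0, 1) # subfield increases first
    pref2 <- abs(cand$pi - p0i)
    pref3 <- cand$pi # then lower priority first
  }
  ord <- order(dist, pref1, pref2, pref3)
  for (j in ord) {
    hit <- tryConfig(2L, .PRIORITY_LEVELS[cand$pi[j]], cand$ni[j])
    if (!is.null(hit)) {
      return(list(
        outcome = "refined", plan = hit$plan, hyperparameters = hit$h,
        stage = 2L, log = do.call(rbind, logRows)
      ))
    }
  }

  list(
    outcome = "reverted", plan = initialPlan, hyperparameters = initialH,
    stage = NA_integer_,
    log = if (length(logRows) > 0) do.call(rbind, logRows) else data.frame()
  )
}

#' Transcribe spoken feedback
#'
#' Thin dispatch onto a speech-to-text backend. The shipped
#' [passthroughTranscriber()] accepts text and returns it unchanged (the
#' offline/test path); an external speech-to-text engine can be plugged in
#' with the same signature. Audio capture itself is outside the package.
#'
#' @param audio Input handed to the backend (text for the passthrough).
#' @param backend `function(audio) -> character`, or `NULL` if none is
#'   configured.
#' @return Transcript text.
#' @export
transcribe <- function(audio, backend = passthroughTranscriber()) {
  if (is.null(backend)) {
    stop("no speech-to-text backend configured; provide the feedback as text")
  }
  backend(audio)
}

#' @rdname transcribe
#' @export
passthroughTranscriber <- function() {
  function(audio) {
    if (!is.character(audio) || length(audio) != 1 || !nzchar(trimws(audio))) {
      stop("passthrough transcriber requires non-empty text input")
    }
    audio
  }
}
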