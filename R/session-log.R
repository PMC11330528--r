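#' Construct a SessionLog
#'
#' Normally produced by [runAgent()] or [generateBehaviour()]; the constructor
#' is exported for tests and for deserialization.
#'
#' @param trials per-trial data.frame (see [SessionLog-class]).
#' @param steps per-step data.frame; defaults to an empty table.
#' @param config the `EnvConfig` used.
#' @param seed integer seed or `NA`.
#' @return a validated `SessionLog`.
#' @export
SessionLog <- function(trials, steps = emptyStepTable(), config = envConfig(),
                       seed = NA_integer_) {
  new("SessionLog", trials = trials, steps = steps, config = unclass(config),
      seed = as.integer(seed))
}

emptyStepTable <- function() {
  data.frame(trial = integer(), block_index = integer(),
             block_type = character(), step = integer(), cue = character(),
             action = character(), reward = numeric(), forced = logical(),
             transition_phase = logical(), delta = numeric())
}

#' @rdname SessionLog-class
#' @aliases trialTable,SessionLog-method
#' @export
setMethod("trialTable", "SessionLog", function(x) x@trials)

#' @rdname SessionLog-class
#' @export
setMethod("stepTable", "SessionLog", function(x) x@steps)

#' @rdname SessionLog-class
#' @details `blockBoundaries()` returns the 0-based global trial indices at
#'   which a new block starts (excluding the session's first block).
#' @export
setMethod("blockBoundaries", "SessionLog", function(x) {
  tr <- x@trials
  tr$trial[tr$trial_in_block == 0 & tr$block_index > 0]
})

#' @rdname SessionLog-class
#' @export
setMethod("sessionConfig", "SessionLog", function(x) x@config)

setMethod("show", "SessionLog", function(object) {
  tr <- object@trials
  cat("SessionLog:", nrow(tr), "trials,", length(unique(tr$block_index)),
      "blocks,", length(blockBoundaries(object)), "transitions\n")
  if (nrow(tr)) {
    cat(sprintf("  relevant-stimulus accuracy: %.3f\n", mean(tr$relevant_correct)))
    cat(sprintf("  mean reward per trial: %.3f\n", mean(tr$reward)))
  }
  if (nrow(object@steps)) cat("  step-level detail recorded\n")
  invisible(NULL)
})

# Convert the raw integer-coded trial list coming out of the C++ simulator
# into the labelled data.frame stored in a SessionLog.
prettyTrials <- function(raw) {
  tr <- as.data.frame(raw)
  tr$block_type <- blockLabel(tr$block_type)
  irr <- rep(NA_character_, nrow(tr))
  shown <- tr$irrelevant_cue > 0
  irr[shown] <- cueLabel(tr$irrelevant_cue[shown])
  tr$irrelevant_cue <- irr
  tr$final_cue <- cueLabel(tr$final_cue)
  for (col in c("transition_phase", "has_irrelevant", "irrelevant_forced",
                "licked_irrelevant", "final_forced", "licked_final",
                "licked_eot", "relevant_correct", "correct", "switched_after",
                "block_cap_hit"))
    tr[[col]] <- as.logical(tr[[col]])
  tr
}

prettySteps <- function(raw) {
  st <- as.data.frame(raw)
  st$block_type <- blockLabel(st$block_type)
  st$cue <- cueLabel(st$cue)
  st$action <- TASK_ACTIONS[st$action + 1L]
  st$forced <- as.logical(st$forced)
  st$transition_phase <- as.logical(st$transition_phase)
  st
}
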