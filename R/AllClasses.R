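#' SessionLog: a behavioural session
#'
#' Ordered record of the trials (and optionally the individual steps) of one
#' simulated or scripted session of the block-switching task. The trial table
#' is the common currency of all behavioural analyses; the step table carries
#' the per-step cue/action/reward detail when it was recorded.
#'
#' @slot trials data.frame with one row per trial: `trial` (0-based global
#'   index), `block_index`, `block_type` (`"VISUAL"`/`"ODOUR"`),
#'   `trial_in_block`, `transition_phase`, `has_irrelevant`, `irrelevant_cue`,
#'   `irrelevant_forced`, `licked_irrelevant`, `final_cue`, `final_forced`,
#'   `licked_final`, `licked_eot`, `relevant_correct`, `correct`, `reward`,
#'   `switched_after`, `block_cap_hit`.
#' @slot steps data.frame with one row per step (may be empty): `trial`,
#'   `block_index`, `block_type`, `step`, `cue`, `action`, `reward`, `forced`,
#'   `transition_phase`, `delta` (TD error of the SARSA update for this
#'   state-action pair, `NA` where no update applied).
#' @slot config the `EnvConfig` list used to generate the session.
#' @slot seed integer seed used (NA if none was set).
#'
#' @seealso [runAgent()], [lickProbabilityCurve()], [summarizeTransitions()]
#' @export
setClass("SessionLog",
  representation(trials = "data.frame", steps = "data.frame",
                 config = "list", seed = "integer"))

setValidity("SessionLog", function(object) {
  tr <- object@trials
  msg <- character()
  need <- c("trial", "block_index", "block_type", "trial_in_block",
            "final_cue", "licked_final", "relevant_correct", "correct",
            "switched_after", "block_cap_hit")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    msg <- c(msg, paste("trials is missing columns:", paste(miss, collapse = ", ")))
  if (nrow(tr) && !length(msg)) {
    bt <- tr$block_type[!duplicated(tr$block_index)]
    if (length(bt) > 1 && any(bt[-1] == bt[-length(bt)]))
      msg <- c(msg, "block types must alternate")
    bb <- tr$trial[tr$trial_in_block == 0]
    if (is.unsorted(bb, strictly = TRUE))
      msg <- c(msg, "block boundaries must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' LickProbabilityCurve: transition-aligned lick probabilities
#'
#' Per-transition lick counts for each cue at each trial position relative to
#' a block transition (position 0 = first trial of the new block). Keeping
#' the counts per transition lets cross-validation folds re-aggregate subsets
#' of transitions without re-computing anything.
#'
#' @slot licks numeric array `transition x cue x position` of lick counts
#'   (0/1 per cell at single-transition resolution).
#' @slot counts numeric array of the same shape; 0 marks a missing cell
#'   (the cue could not occur at that position, e.g. during forced trials).
#' @slot direction character per transition, `"odour_to_visual"` or
#'   `"visual_to_odour"`.
#' @slot window integer half-width W; positions run -W..W.
#' @export
setClass("LickProbabilityCurve",
  representation(licks = "array", counts = "array",
                 direction = "character", window = "integer"))

setValidity("LickProbabilityCurve", function(object) {
  d <- dim(object@licks)
  msg <- character()
  if (!identical(d, dim(object@counts)))
    msg <- c(msg, "licks and counts must have identical dimensions")
  if (length(d) != 3 || d[2] != 4 || d[3] != 2L * object@window + 1L)
    msg <- c(msg, "arrays must be transition x 4 cues x (2*window+1) positions")
  if (length(object@direction) != d[1])
    msg <- c(msg, "direction must have one entry per transition")
  if (any(object@counts < 0) || any(object@licks > object@counts))
    msg <- c(msg, "licks must lie in [0, counts]")
  if (length(msg)) msg else TRUE
})

#' CalciumRecording: dF/F matrix with event annotation
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `"dff"` assay holds
#' the neurons x frames dF/F matrix, extended with the acquisition rate, a
#' task-event table and a per-trial annotation table. Per-frame covariates
#' (running speed, a binarised lick trace) live in `colData`; per-neuron
#' metadata (e.g. ground-truth class for synthetic recordings, projection
#' labels) in `rowData`.
#'
#' @slot frameRate acquisition rate in Hz.
#' @slot events DataFrame of task events: `type`, `time_s`, `trial`.
#' @slot trialInfo DataFrame with one row per trial: block structure, cues,
#'   lick outcomes and the stimulus times used to align epochs.
#' @export
setClass("CalciumRecording",
  contains = "SummarizedExperiment",
  representation(frameRate = "numeric", events = "DataFrame",
                 trialInfo = "DataFrame"))

setValidity("CalciumRecording", function(object) {
  msg <- character()
  if (length(object@frameRate) != 1 || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (!"dff" %in% names(assays(object)))
    msg <- c(msg, "a 'dff' assay is required")
  if (!all(c("type", "time_s") %in% colnames(object@events)))
    msg <- c(msg, "events needs 'type' and 'time_s' columns")
  if (length(msg)) msg else TRUE
})
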