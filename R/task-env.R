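#' Task-environment configuration
#'
#' Parameters of the discrete-step block-switching environment: a visual
#' go/no-go block and an odour go/no-go block in which 70% of odour trials
#' are preceded by a task-irrelevant grating. A block ends once the agent
#' exceeds 80% accuracy on the relevant stimuli over the last 30 trials and,
#' in odour blocks, has ignored every irrelevant grating over the last 10
#' trials; after each switch a transition period forces the stimulus
#' sequence until the agent proves it has adopted the new rule.
#'
#' @param pIrrelevantVisual probability that an odour trial is preceded by an
#'   irrelevant grating (default 0.70).
#' @param blockAccuracyThreshold accuracy that must be strictly exceeded over
#'   the accuracy window for a block to end (default 0.80).
#' @param blockAccuracyWindow number of trials in the accuracy window (30).
#' @param ignoreWindow number of trials over which all irrelevant gratings
#'   must have been ignored in odour blocks (10).
#' @param transitionVariant `"V1"` (first forced irrelevant grating after a
#'   visual-to-odour switch is the unrewarded VISUAL_2, the rest VISUAL_1) or
#'   `"V2"` (all forced irrelevant gratings are VISUAL_1).
#' @param rewardCorrect,punish reward magnitudes (+1 / -1); informational,
#'   the environment emits exactly these values.
#' @param maxBlockTrials safety cap: a block that never meets the criteria
#'   (e.g. under a random agent) is force-ended after this many trials and
#'   flagged `block_cap_hit` in the log (default 500).
#' @param firstBlock block type the session starts in (default `"VISUAL"`).
#' @param forcedTrials 0 (default) applies the rule that forcing lasts until
#'   three consecutive correct responses; a positive integer instead forces
#'   exactly that many initial trials of each block.
#' @param seed optional integer seed used by [envReset()].
#' @return a validated list of class `"EnvConfig"`.
#' @export
envConfig <- function(pIrrelevantVisual = 0.70, blockAccuracyThreshold = 0.80,
                      blockAccuracyWindow = 30L, ignoreWindow = 10L,
                      transitionVariant = c("V1", "V2"), rewardCorrect = 1,
                      punish = -1, maxBlockTrials = 500L,
                      firstBlock = c("VISUAL", "ODOUR"), forcedTrials = 0L,
                      seed = NULL) {
  transitionVariant <- match.arg(transitionVariant)
  firstBlock <- match.arg(firstBlock)
  if (!is.numeric(pIrrelevantVisual) || pIrrelevantVisual < 0 ||
      pIrrelevantVisual > 1)
    stop("pIrrelevantVisual must be a probability in [0, 1]")
  if (!is.numeric(blockAccuracyThreshold) || blockAccuracyThreshold < 0 ||
      blockAccuracyThreshold > 1)
    stop("blockAccuracyThreshold must be a fraction in [0, 1]")
  if (blockAccuracyWindow < 1 || ignoreWindow < 1)
    stop("criterion windows must be positive")
  if (maxBlockTrials < blockAccuracyWindow)
    stop("maxBlockTrials must be at least blockAccuracyWindow")
  structure(list(
    pIrrelevantVisual = pIrrelevantVisual,
    blockAccuracyThreshold = blockAccuracyThreshold,
    blockAccuracyWindow = as.integer(blockAccuracyWindow),
    ignoreWindow = as.integer(ignoreWindow),
    transitionVariant = transitionVariant,
    rewardCorrect = rewardCorrect, punish = punish,
    maxBlockTrials = as.integer(maxBlockTrials),
    firstBlock = firstBlock, forcedTrials = as.integer(forcedTrials),
    seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "EnvConfig")
}

# integer-coded view handed to the C++ simulator
envConfigCodes <- function(cfg) {
  list(pIrrelevantVisual = cfg$pIrrelevantVisual,
       blockAccuracyThreshold = cfg$blockAccuracyThreshold,
       blockAccuracyWindow = cfg$blockAccuracyWindow,
       ignoreWindow = cfg$ignoreWindow,
       transitionVariantCode = if (cfg$transitionVariant == "V1") 1L else 2L,
       maxBlockTrials = cfg$maxBlockTrials,
       forcedTrials = cfg$forcedTrials,
       firstBlockCode = if (cfg$firstBlock == "VISUAL") 0L else 1L)
}

#' Reset the task environment
#'
#' Returns the initial environment state: the session starts in the
#' configured first block at trial 0, step 0 (the end-of-trial cue of the
#' preceding, notional trial), outside any transition period. If the config
#' carries a seed the R random number generator is seeded, so two resets with
#' the same seed reproduce the same cue sequence.
#'
#' @param config an [envConfig()].
#' @return an environment-state list; pass it to [envStep()].
#' @examples
#' st <- envReset(envConfig(seed = 7))
#' out <- envStep(st, "NO_LICK")
#' out$outcome$cuePresented
#' @export
envReset <- function(config = envConfig()) {
  if (!inherits(config, "EnvConfig")) stop("config must come from envConfig()")
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- list(config = config,
                blockType = config$firstBlock, blockIndex = 0L,
                trialInBlock = 0L, stepInTrial = 0L,
                inTransition = FALSE, consecutiveCorrect = 0L,
                firstIrrShown = FALSE,
                relCorrectHist = logical(), irrStatusHist = integer(),
                trialCues = NULL, trialForced = NULL,
                trialLicks = logical(), blockJustSwitched = FALSE)
  startTrial(state)
}

# draw the cue sequence for the trial about to start
startTrial <- function(state) {
  cfg <- state$config
  forcing <- if (cfg$forcedTrials > 0L) state$trialInBlock < cfg$forcedTrials
             else state$inTransition
  cues <- "END_OF_TRIAL"
  forced <- FALSE
  if (state$blockType == "VISUAL") {
    cue <- if (forcing) "VISUAL_1"
           else if (runif(1) < 0.5) "VISUAL_1" else "VISUAL_2"
    cues <- c(cues, cue)
    forced <- c(forced, forcing)
  } else {
    hasIrr <- runif(1) < cfg$pIrrelevantVisual
    if (hasIrr) {
      if (forcing) {
        cue <- scheduleForcedIrrelevant(state$firstIrrShown, cfg$transitionVariant)
        state$firstIrrShown <- TRUE
      } else {
        cue <- if (runif(1) < 0.5) "VISUAL_1" else "VISUAL_2"
        state$firstIrrShown <- TRUE
      }
      cues <- c(cues, cue)
      forced <- c(forced, forcing)
    }
    cues <- c(cues, if (runif(1) < 0.5) "ODOUR_1" else "ODOUR_2")
    forced <- c(forced, FALSE)
  }
  state$trialCues <- cues
  state$trialForced <- forced
  state$trialLicks <- logical(length(cues))
  state$stepInTrial <- 0L
  state$transitionAtTrialStart <- forcing
  state
}

scheduleForcedIrrelevant <- function(firstIrrShown, variant) {
  if (variant == "V1" && !firstIrrShown) "VISUAL_2" else "VISUAL_1"
}

#' Schedule the forced cue of a transition-period trial
#'
#' After an odour-to-visual switch only the rewarded grating VISUAL_1 is
#' shown until the agent licks correctly on three consecutive trials. After a
#' visual-to-odour switch the forced irrelevant grating is VISUAL_2 on its
#' first appearance under variant `"V1"` (so the switch is signalled by the
#' unexpected odour, not a reward prediction error) and VISUAL_1 otherwise;
#' under variant `"V2"` it is always VISUAL_1. Odour identity is never forced.
#'
#' @param state an environment state currently inside a transition period.
#' @param config the environment config (defaults to the state's own).
#' @return the forced `TaskCue` for the next stimulus slot.
#' @export
scheduleTransitionCue <- function(state, config = state$config) {
  if (!isTRUE(state$inTransition) && config$forcedTrials == 0L)
    stop("scheduleTransitionCue() called outside a transition period")
  if (state$blockType == "VISUAL") "VISUAL_1"
  else scheduleForcedIrrelevant(state$firstIrrShown, config$transitionVariant)
}

#' Advance the environment by one step
#'
#' The agent acts on the currently presented cue. A lick at any non-final
#' step (the end-of-trial cue or an irrelevant grating) is a needless lick,
#' punished with -1. At the final (reward) step a lick earns +1 for the
#' rewarded cue (VISUAL_1 in visual blocks, ODOUR_1 in odour blocks) and -1
#' for the unrewarded one; withholding the lick always yields 0. Block
#' switching is evaluated at trial end via [checkBlockSwitch()].
#'
#' @param state state from [envReset()] or a previous `envStep()`.
#' @param action `"LICK"` or `"NO_LICK"`.
#' @return list with elements `state` (advanced state) and `outcome`: a list
#'   with `reward`, `trialEnded`, `blockSwitched`, `cuePresented` (the cue
#'   acted upon) and `forcedCue`.
#' @export
envStep <- function(state, action) {
  if (!action %in% TASK_ACTIONS) stop("unknown action: ", action)
  lick <- action == "LICK"
  k <- state$stepInTrial + 1L
  cue <- state$trialCues[k]
  isFinal <- k == length(state$trialCues)
  reward <- if (isFinal) {
    if (lick) (if (cue %in% c("VISUAL_1", "ODOUR_1")) 1 else -1) else 0
  } else if (lick) -1 else 0
  state$trialLicks[k] <- lick
  outcome <- list(reward = reward, trialEnded = isFinal, blockSwitched = FALSE,
                  cuePresented = cue, forcedCue = state$trialForced[k])
  if (!isFinal) {
    state$stepInTrial <- k
    return(list(state = state, outcome = outcome))
  }
  # ---- trial end ----
  cfg <- state$config
  relCorrect <- if (cue %in% c("VISUAL_1", "ODOUR_1")) lick else !lick
  irrIdx <- which(isVisualCue(state$trialCues) & state$blockType == "ODOUR")
  hasIrr <- length(irrIdx) > 0
  lickedIrr <- hasIrr && any(state$trialLicks[irrIdx])
  state$relCorrectHist <- c(state$relCorrectHist, relCorrect)
  state$irrStatusHist <- c(state$irrStatusHist,
                           if (!hasIrr) -1L else if (lickedIrr) 0L else 1L)
  # transition-period counter (until-3-correct rule)
  if (state$inTransition && cfg$forcedTrials == 0L) {
    if (state$blockType == "VISUAL") {
      state$consecutiveCorrect <- if (lick) state$consecutiveCorrect + 1L else 0L
    } else if (hasIrr) {
      state$consecutiveCorrect <- if (lickedIrr) 0L else state$consecutiveCorrect + 1L
    }
    if (state$consecutiveCorrect >= 3L) state$inTransition <- FALSE
  }
  blockTrials <- data.frame(relevant_correct = state$relCorrectHist,
                            has_irrelevant = state$irrStatusHist != -1L,
                            licked_irrelevant = state$irrStatusHist == 0L)
  switched <- checkBlockSwitch(blockTrials, cfg,
                               blockType = state$blockType)
  capHit <- !switched && nrow(blockTrials) >= cfg$maxBlockTrials
  if (capHit) switched <- TRUE
  state$trialInBlock <- state$trialInBlock + 1L
  if (switched) {
    state$blockType <- setdiff(BLOCK_TYPES, state$blockType)
    state$blockIndex <- state$blockIndex + 1L
    state$trialInBlock <- 0L
    state$inTransition <- TRUE
    state$consecutiveCorrect <- 0L
    state$firstIrrShown <- FALSE
    state$relCorrectHist <- logical()
    state$irrStatusHist <- integer()
  }
  outcome$blockSwitched <- switched
  outcome$blockCapHit <- capHit
  list(state = startTrial(state), outcome = outcome)
}

#' Block-switch criterion
#'
#' TRUE iff strictly more than `blockAccuracyThreshold` of the responses to
#' relevant stimuli were correct over the last `blockAccuracyWindow` trials
#' of the current block and, for odour blocks, every irrelevant grating over
#' the last `ignoreWindow` trials was ignored. Returns FALSE while fewer
#' than `blockAccuracyWindow` trials exist.
#'
#' @param blockTrials data.frame for the current block only, in trial order,
#'   with columns `relevant_correct`, `has_irrelevant`, `licked_irrelevant`.
#' @param config an [envConfig()].
#' @param blockType `"VISUAL"` or `"ODOUR"`.
#' @return logical scalar.
#' @export
checkBlockSwitch <- function(blockTrials, config = envConfig(),
                             blockType = c("VISUAL", "ODOUR")) {
  blockType <- match.arg(blockType)
  n <- nrow(blockTrials)
  if (n < config$blockAccuracyWindow) return(FALSE)
  acc <- mean(tail(blockTrials$relevant_correct, config$blockAccuracyWindow))
  if (acc <= config$blockAccuracyThreshold) return(FALSE)
  if (blockType == "ODOUR") {
    recent <- tail(blockTrials, config$ignoreWindow)
    if (any(recent$has_irrelevant & recent$licked_irrelevant)) return(FALSE)
  }
  TRUE
}
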