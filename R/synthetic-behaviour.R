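#' Default scripted lick-probability table
#'
#' Lick probability per cue under each *applied rule* (which block's rule
#' the animal is currently following). Under the visual rule the rewarded
#' grating is licked (0.95) and the unrewarded one mostly not (0.05); under
#' the odour rule gratings are ignored (0.03) and the rewarded odour is
#' licked (0.97). Odour cues only ever occur under the odour rule.
#'
#' @return 5 x 2 matrix, rows [TASK_CUES], columns [BLOCK_TYPES].
#' @export
defaultLickProbTable <- function() {
  m <- matrix(c(0.95, 0.03,
                0.05, 0.03,
                NA,   0.97,
                NA,   0.03,
                0.02, 0.02),
              nrow = 5, byrow = TRUE,
              dimnames = list(TASK_CUES, BLOCK_TYPES))
  m
}

#' Synthetic-behaviour configuration
#'
#' Two generation modes. `agent_driven` runs the belief-state agent in the
#' task environment (train then frozen test), so switching dynamics emerge
#' from the model; the default agent parameters are the best-fit values of
#' the primary dataset. `scripted_policy` emits licks i.i.d. from a per-cue
#' probability table with a deterministic rule switch a controllable number
#' of trials after each block boundary, giving exact control over the
#' one-shot fraction for testing.
#'
#' @param mode `"agent_driven"` or `"scripted_policy"`.
#' @param agentParams [beliefAgentParams()] (agent_driven mode).
#' @param envCfg [envConfig()] (agent_driven mode).
#' @param nTrainSteps,nTestSteps steps per phase (agent_driven mode).
#' @param lickProb 5 x 2 per-cue, per-rule lick-probability table
#'   (scripted mode); see [defaultLickProbTable()].
#' @param nBlocks,trialsPerBlock scripted block schedule (`trialsPerBlock`
#'   is recycled over blocks).
#' @param oneShotFraction probability that a scripted transition switches
#'   rule after exactly one trial; otherwise after `slowSwitchLag` trials.
#' @param slowSwitchLag rule lag of non-one-shot scripted transitions.
#' @param pIrrelevantVisual irrelevant-grating probability in scripted odour
#'   trials.
#' @param seed integer seed.
#' @return list of class `"SyntheticBehaviourConfig"`.
#' @export
syntheticBehaviourConfig <- function(mode = c("agent_driven", "scripted_policy"),
                                     agentParams = beliefAgentParams(),
                                     envCfg = envConfig(),
                                     nTrainSteps = 50000L, nTestSteps = 50000L,
                                     lickProb = defaultLickProbTable(),
                                     nBlocks = 10L, trialsPerBlock = 30L,
                                     oneShotFraction = 1.0, slowSwitchLag = 3L,
                                     pIrrelevantVisual = 0.70, seed = 1L) {
  mode <- match.arg(mode)
  pr <- lickProb[!is.na(lickProb)]
  stopifnot(all(pr >= 0 & pr <= 1), oneShotFraction >= 0, oneShotFraction <= 1,
            nBlocks >= 1, all(trialsPerBlock >= 1), slowSwitchLag >= 0)
  structure(list(mode = mode, agentParams = agentParams, envCfg = envCfg,
                 nTrainSteps = as.integer(nTrainSteps),
                 nTestSteps = as.integer(nTestSteps), lickProb = lickProb,
                 nBlocks = as.integer(nBlocks),
                 trialsPerBlock = as.integer(trialsPerBlock),
                 oneShotFraction = oneShotFraction,
                 slowSwitchLag = as.integer(slowSwitchLag),
                 pIrrelevantVisual = pIrrelevantVisual,
                 seed = as.integer(seed)),
            class = "SyntheticBehaviourConfig")
}

scriptedTrials <- function(cfg) {
  lens <- rep_len(cfg$trialsPerBlock, cfg$nBlocks)
  lp <- cfg$lickProb
  rows <- list()
  trial <- 0L
  for (b in seq_len(cfg$nBlocks)) {
    btype <- BLOCK_TYPES[(b - 1L) %% 2L + 1L]
    prevType <- if (b == 1L) btype else BLOCK_TYPES[b %% 2L + 1L]
    lag <- if (b == 1L) 0L
           else if (runif(1) < cfg$oneShotFraction) 1L else cfg$slowSwitchLag
    for (t in seq_len(lens[b])) {
      rule <- if (t <= lag) prevType else btype
      hasIrr <- FALSE; irrCue <- NA_character_; lickedIrr <- FALSE
      forcedFinal <- FALSE
      if (btype == "VISUAL") {
        # first three trials of a visual block show the rewarded grating, as
        # in the task's transition period
        forcedFinal <- b > 1L && t <= 3L
        finalCue <- if (forcedFinal) "VISUAL_1"
                    else if (runif(1) < 0.5) "VISUAL_1" else "VISUAL_2"
        lickedFinal <- runif(1) < lp[finalCue, rule]
      } else {
        hasIrr <- runif(1) < cfg$pIrrelevantVisual
        if (hasIrr) {
          irrCue <- if (runif(1) < 0.5) "VISUAL_1" else "VISUAL_2"
          lickedIrr <- runif(1) < lp[irrCue, rule]
        }
        finalCue <- if (runif(1) < 0.5) "ODOUR_1" else "ODOUR_2"
        lickedFinal <- runif(1) < lp[finalCue, "ODOUR"]
      }
      lickedEot <- runif(1) < lp["END_OF_TRIAL", rule]
      relCorrect <- if (finalCue %in% c("VISUAL_1", "ODOUR_1")) lickedFinal
                    else !lickedFinal
      reward <- (if (lickedFinal)
                   (if (finalCue %in% c("VISUAL_1", "ODOUR_1")) 1 else -1)
                 else 0) - lickedEot - lickedIrr
      rows[[length(rows) + 1L]] <- data.frame(
        trial = trial, block_index = b - 1L, block_type = btype,
        trial_in_block = t - 1L, transition_phase = FALSE,
        has_irrelevant = hasIrr, irrelevant_cue = irrCue,
        irrelevant_forced = FALSE, licked_irrelevant = lickedIrr,
        final_cue = finalCue, final_forced = forcedFinal,
        licked_final = lickedFinal, licked_eot = lickedEot,
        relevant_correct = relCorrect,
        correct = relCorrect && !lickedEot && !lickedIrr,
        reward = reward,
        switched_after = t == lens[b] && b < cfg$nBlocks,
        block_cap_hit = FALSE)
      trial <- trial + 1L
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic behavioural session
#'
#' @param cfg a [syntheticBehaviourConfig()].
#' @return list with `log` (a [SessionLog]), `trace` (belief trace in
#'   agent_driven mode, else NULL) and `truth` (generative parameters and,
#'   in scripted mode, the rule-switch lags per transition).
#' @export
generateBehaviour <- function(cfg = syntheticBehaviourConfig()) {
  stopifnot(inherits(cfg, "SyntheticBehaviourConfig"))
  set.seed(cfg$seed)
  if (cfg$mode == "agent_driven") {
    sim <- simulateExperiment(cfg$agentParams, cfg$nTrainSteps, cfg$nTestSteps,
                              envCfg = cfg$envCfg)
    truth <- list(mode = cfg$mode, params = cfg$agentParams, seed = cfg$seed)
    list(log = sim$log, trace = sim$trace, truth = truth)
  } else {
    tr <- scriptedTrials(cfg)
    log <- SessionLog(tr, config = cfg$envCfg, seed = cfg$seed)
    truth <- list(mode = cfg$mode, lickProb = cfg$lickProb,
                  oneShotFraction = cfg$oneShotFraction, seed = cfg$seed)
    list(log = log, trace = NULL, truth = truth)
  }
}
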