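# drive the pure-R environment with a fixed policy and collect per-trial info
runPolicyR <- function(config, policy, nTrials) {
  st <- envReset(config)
  trials <- list()
  cur <- list(cues = character(), rewards = numeric(), forced = logical(),
              block = st$blockType, blockIndex = st$blockIndex)
  while (length(trials) < nTrials) {
    cue <- st$trialCues[st$stepInTrial + 1L]
    act <- policy(cue, st$blockType)
    res <- envStep(st, act)
    cur$cues <- c(cur$cues, res$outcome$cuePresented)
    cur$rewards <- c(cur$rewards, res$outcome$reward)
    cur$forced <- c(cur$forced, res$outcome$forcedCue)
    if (res$outcome$trialEnded) {
      cur$blockSwitched <- res$outcome$blockSwitched
      trials[[length(trials) + 1L]] <- cur
      st <- res$state
      cur <- list(cues = character(), rewards = numeric(), forced = logical(),
                  block = st$blockType, blockIndex = st$blockIndex)
    } else st <- res$state
  }
  trials
}

# an agent that always responds correctly (licks rewarded cues, ignores the rest)
perfectPolicy <- function(cue, blockType) {
  if (cue == "VISUAL_1" && blockType == "VISUAL") "LICK"
  else if (cue == "ODOUR_1") "LICK"
  else "NO_LICK"
}

# minimal scripted session with exact control, via the scripted generator
scriptedSession <- function(nBlocks = 6, trialsPerBlock = 30, seed = 1,
                            oneShotFraction = 1, ...) {
  generateBehaviour(syntheticBehaviourConfig(
    mode = "scripted_policy", nBlocks = nBlocks,
    trialsPerBlock = trialsPerBlock, oneShotFraction = oneShotFraction,
    seed = seed, ...))
}

# hand-built trial table for curve/behaviour counting oracles
handTrialTable <- function(blockType, finalCue, lickedFinal,
                           irrCue = NA, lickedIrr = FALSE) {
  n <- length(finalCue)
  blocks <- cumsum(c(0, blockType[-1] != blockType[-n]))
  data.frame(trial = seq_len(n) - 1L, block_index = blocks,
             block_type = blockType,
             trial_in_block = stats::ave(seq_len(n), blocks, FUN = seq_along) - 1L,
             transition_phase = FALSE,
             has_irrelevant = !is.na(irrCue),
             irrelevant_cue = as.character(irrCue), irrelevant_forced = FALSE,
             licked_irrelevant = lickedIrr, final_cue = finalCue,
             final_forced = FALSE, licked_final = lickedFinal,
             licked_eot = FALSE,
             relevant_correct = ifelse(finalCue %in% c("VISUAL_1", "ODOUR_1"),
                                       lickedFinal, !lickedFinal),
             correct = NA, reward = 0,
             switched_after = c(blocks[-1] != blocks[-n], FALSE),
             block_cap_hit = FALSE)
}
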