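test_that("reward semantics follow the task's reward table", {
  cases <- list(
    # final step, visual block: lick to rewarded grating -> +1
    list(block = "VISUAL", cues = c("END_OF_TRIAL", "VISUAL_1"),
         actions = c("NO_LICK", "LICK"), rewards = c(0, 1)),
    # final step, lick to unrewarded grating -> -1
    list(block = "VISUAL", cues = c("END_OF_TRIAL", "VISUAL_2"),
         actions = c("NO_LICK", "LICK"), rewards = c(0, -1)),
    # no lick always 0, including unrewarded odour
    list(block = "ODOUR", cues = c("END_OF_TRIAL", "ODOUR_2"),
         actions = c("NO_LICK", "NO_LICK"), rewards = c(0, 0)),
    # needless licks at non-final steps -> -1 (end-of-trial and irrelevant cue)
    list(block = "ODOUR", cues = c("END_OF_TRIAL", "VISUAL_1", "ODOUR_1"),
         actions = c("LICK", "LICK", "LICK"), rewards = c(-1, -1, 1)))
  for (cs in cases) {
    st <- envReset(envConfig(seed = 1, firstBlock = cs$block))
    # overwrite the drawn trial with the scripted cue sequence
    st$trialCues <- cs$cues
    st$trialForced <- rep(FALSE, length(cs$cues))
    st$trialLicks <- logical(length(cs$cues))
    for (k in seq_along(cs$cues)) {
      out <- envStep(st, cs$actions[k])
      expect_identical(out$outcome$cuePresented, cs$cues[k])
      expect_identical(out$outcome$reward, cs$rewards[k])
      expect_identical(out$outcome$trialEnded, k == length(cs$cues))
      st <- out$state
    }
  }
})

test_that("rewards stay in {-1, 0, +1} with one reward per step", {
  res <- runAgent(beliefAgentParams(), nSteps = 3000, phase = "train",
                  seed = 9, recordSteps = TRUE)
  st <- stepTable(res$log)
  expect_true(all(st$reward %in% c(-1, 0, 1)))
  expect_identical(nrow(st), sum(!is.na(st$reward)))
})

test_that("seeded resets reproduce the same cue sequence", {
  draw <- function() {
    st <- envReset(envConfig(seed = 7))
    cues <- character()
    for (i in 1:100) {
      out <- envStep(st, "NO_LICK")
      cues <- c(cues, out$outcome$cuePresented)
      st <- out$state
    }
    cues
  }
  expect_identical(draw(), draw())
})

test_that("irrelevant-cue forcing probability controls odour-trial length", {
  countSteps <- function(p) {
    trials <- runPolicyR(envConfig(seed = 3, firstBlock = "ODOUR",
                                   pIrrelevantVisual = p),
                         perfectPolicy, 40)
    lengths <- vapply(trials, function(t) length(t$cues), integer(1))
    odour <- vapply(trials, function(t) t$block == "ODOUR", logical(1))
    lengths[odour]
  }
  expect_true(all(countSteps(1.0) == 3))  # every odour trial shows a grating
  expect_true(all(countSteps(0.0) == 2))
  # long-run 3-step fraction at the default 0.70 (fast path)
  sim <- runAgent(beliefAgentParams(), nSteps = 40000, phase = "train",
                  seed = 21)
  tr <- trialTable(sim$log)
  frac <- mean(tr$has_irrelevant[tr$block_type == "ODOUR"])
  expect_gt(sum(tr$block_type == "ODOUR"), 5000)
  expect_lt(abs(frac - 0.70), 0.02)
})

test_that("block-switch criterion uses a strict threshold and both windows", {
  cfg <- envConfig()
  mk <- function(corr, hasIrr = FALSE, lickedIrr = FALSE)
    data.frame(relevant_correct = corr,
               has_irrelevant = rep_len(hasIrr, length(corr)),
               licked_irrelevant = rep_len(lickedIrr, length(corr)))
  # 29 trials: window not filled
  expect_false(checkBlockSwitch(mk(rep(TRUE, 29)), cfg, "VISUAL"))
  # exactly 24/30 = 80%: strict inequality fails
  expect_false(checkBlockSwitch(mk(c(rep(TRUE, 24), rep(FALSE, 6))), cfg, "VISUAL"))
  expect_true(checkBlockSwitch(mk(c(rep(FALSE, 5), rep(TRUE, 25))), cfg, "VISUAL"))
  # exhaustive small-case check of the strict 80% rule on the last 30 trials
  for (nc in 22:30) {
    trials <- mk(sample(c(rep(TRUE, nc), rep(FALSE, 30 - nc))))
    expect_identical(checkBlockSwitch(trials, cfg, "VISUAL"), nc / 30 > 0.8)
  }
  # odour block: one licked irrelevant cue in the last 10 trials blocks the switch
  tr <- mk(rep(TRUE, 30), hasIrr = TRUE, lickedIrr = FALSE)
  expect_true(checkBlockSwitch(tr, cfg, "ODOUR"))
  tr$licked_irrelevant[25] <- TRUE   # within the last 10
  expect_false(checkBlockSwitch(tr, cfg, "ODOUR"))
  tr$licked_irrelevant[25] <- FALSE
  tr$licked_irrelevant[15] <- TRUE   # outside the last 10: no effect
  expect_true(checkBlockSwitch(tr, cfg, "ODOUR"))
})

test_that("a perfect-policy agent yields minimum-length, alternating blocks", {
  # brute-force oracle: with every response correct, each block must end
  # exactly when the 30-trial accuracy window fills
  trials <- runPolicyR(envConfig(seed = 5), perfectPolicy, 5 * 30 + 1)
  blockIdx <- vapply(trials, `[[`, integer(1), "blockIndex")
  lens <- as.integer(table(blockIdx))[1:5]
  expect_identical(lens, rep(30L, 5))
  types <- vapply(trials, `[[`, character(1), "block")[!duplicated(blockIdx)]
  expect_identical(types[1:6], rep(c("VISUAL", "ODOUR"), 3))
})

test_that("transition periods force the scheduled cues", {
  # odour -> visual: forced VISUAL_1 until three consecutive correct licks
  trials <- runPolicyR(envConfig(seed = 11), perfectPolicy, 95)
  idx2 <- which(vapply(trials, `[[`, integer(1), "blockIndex") == 2)
  firstVis <- trials[idx2[1:3]]
  for (t in firstVis) {
    expect_identical(t$cues[2], "VISUAL_1")
    expect_true(t$forced[2])
  }
  expect_false(trials[[idx2[4]]]$forced[2])  # forcing released after 3 correct

  # visual -> odour, variant V1: first irrelevant grating is VISUAL_2
  trialsB <- runPolicyR(envConfig(seed = 12, transitionVariant = "V1",
                                  pIrrelevantVisual = 1), perfectPolicy, 65)
  idx1 <- which(vapply(trialsB, `[[`, integer(1), "blockIndex") == 1)
  expect_identical(trialsB[[idx1[1]]]$cues[2], "VISUAL_2")
  expect_true(trialsB[[idx1[1]]]$forced[2])
  expect_identical(trialsB[[idx1[2]]]$cues[2], "VISUAL_1")

  # variant V2: all forced irrelevant cues are VISUAL_1
  trialsC <- runPolicyR(envConfig(seed = 12, transitionVariant = "V2",
                                  pIrrelevantVisual = 1), perfectPolicy, 65)
  idx1C <- which(vapply(trialsC, `[[`, integer(1), "blockIndex") == 1)
  expect_identical(trialsC[[idx1C[1]]]$cues[2], "VISUAL_1")
})

test_that("after forcing ends the grating identity returns to 50/50", {
  sim <- runAgent(beliefAgentParams(), nSteps = 60000, phase = "train", seed = 31)
  tr <- trialTable(sim$log)
  vis <- tr[tr$block_type == "VISUAL" & !tr$final_forced, ]
  expect_gt(nrow(vis), 5000)
  expect_lt(abs(mean(vis$final_cue == "VISUAL_1") - 0.5), 0.02)
})

test_that("fixed-count forcing variant is available", {
  trials <- runPolicyR(envConfig(seed = 2, forcedTrials = 3),
                       function(cue, b) "NO_LICK", 40)
  # an always-wrong agent: forcing still ends after exactly 3 trials
  expect_true(all(vapply(trials[1:3], function(t) t$forced[2], logical(1))))
  expect_false(trials[[4]]$forced[2])
})

test_that("the C++ fast path matches the R environment on deterministic runs", {
  # same perfect-behaviour structure: blocks of exactly 30 trials; the fast
  # path is checked via a zero-exploration greedy agent after convergence
  sim <- simulateExperiment(beliefAgentParams(zeta = 1, beta = 0, epsilon = 0,
                                              epsilonPrime = 0),
                            20000, 6000, seed = 17)
  tr <- trialTable(sim$log)
  lens <- table(tr$block_index)
  inner <- lens[-c(1, length(lens))]
  expect_true(all(inner >= 30))
  expect_gt(mean(inner <= 31), 0.9)  # near-minimal blocks once converged
})

test_that("same seed and parameters give bit-identical session logs", {
  a <- runAgent(beliefAgentParams(), nSteps = 5000, phase = "train", seed = 77,
                recordSteps = TRUE)
  b <- runAgent(beliefAgentParams(), nSteps = 5000, phase = "train", seed = 77,
                recordSteps = TRUE)
  expect_identical(trialTable(a$log), trialTable(b$log))
  expect_identical(stepTable(a$log), stepTable(b$log))
  expect_identical(a$trace, b$trace)
})
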