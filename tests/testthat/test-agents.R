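test_that("epsilon-greedy selection is greedy, explores, and breaks ties", {
  set.seed(1)
  expect_identical(selectAction(c(NO_LICK = 0, LICK = 1), epsilon = 0), "LICK")
  expect_identical(selectAction(c(NO_LICK = 2, LICK = 1), epsilon = 0), "NO_LICK")
  expect_error(selectAction(c(0, 1), epsilon = 1.2), "epsilon")
  expect_error(selectAction(c(0, 1, 2), epsilon = 0), "2 entries")
  lickFrac <- function(q, eps, n = 10000)
    mean(vapply(seq_len(n), function(i) selectAction(q, eps) == "LICK",
                logical(1)))
  expect_lt(abs(lickFrac(c(0, 1), eps = 1) - 0.5), 0.02)   # pure exploration
  expect_lt(abs(lickFrac(c(0.3, 0.3), eps = 0) - 0.5), 0.02)  # tie break
})

test_that("sarsaUpdate reproduces the TD rule exactly", {
  # independent scalar oracle for delta and the update
  oracle <- function(qsa, r, qnext, alpha)
    list(delta = r + qnext - qsa, qnew = qsa + alpha * (r + qnext - qsa))
  q <- newQTable()
  up <- sarsaUpdate(q, "VISUAL_1", "LICK", r = 1, sNext = "END_OF_TRIAL",
                    aNext = "NO_LICK", alpha = 0.1)
  o <- oracle(0, 1, 0, 0.1)
  expect_equal(up$tdError$delta, o$delta)          # 1
  expect_equal(up$q["VISUAL_1", "LICK"], o$qnew)   # 0.1
  # fixed point: r = 0 and equal Q values leave the table unchanged
  q2 <- newQTable(); q2["ODOUR_1", "LICK"] <- 0.4; q2["VISUAL_2", "NO_LICK"] <- 0.4
  up2 <- sarsaUpdate(q2, "ODOUR_1", "LICK", 0, "VISUAL_2", "NO_LICK", 0.5)
  expect_equal(up2$tdError$delta, 0)
  expect_identical(up2$q, q2)
  # zero learning rate: delta reported, Q untouched
  up3 <- sarsaUpdate(q2, "ODOUR_1", "LICK", 5, "VISUAL_2", "NO_LICK", 0)
  expect_identical(up3$q, q2)
  expect_equal(up3$tdError$delta, 5)
  # randomized cross-check against the oracle
  set.seed(2)
  for (i in 1:25) {
    q <- newQTable(); q[] <- rnorm(8)
    s <- sample(TASK_CUES[1:4], 1); a <- sample(TASK_ACTIONS, 1)
    sn <- sample(TASK_CUES, 1); an <- sample(TASK_ACTIONS, 1)
    r <- sample(c(-1, 0, 1), 1); al <- runif(1)
    qnext <- if (sn == "END_OF_TRIAL") 0 else q[sn, an]
    o <- oracle(q[s, a], r, qnext, al)
    up <- sarsaUpdate(q, s, a, r, sn, an, al)
    expect_equal(up$tdError$delta, o$delta)
    expect_equal(up$q[s, a], o$qnew)
  }
})

test_that("mismatch signal is d - b and always sums to zero", {
  expect_equal(computeMismatch(c(1, 0), c(1, 0)), c(0, 0))
  expect_equal(computeMismatch(c(0, 1), c(1, 0)), c(1, -1))
  expect_equal(computeMismatch(c(0.3, 0.7), c(0, 1)), c(-0.3, 0.3))
  expect_error(computeMismatch(c(0.5, 0.5), c(1, 1)), "one-hot")
  set.seed(3)
  for (i in 1:50) {
    b <- runif(1); d <- sample(list(c(1, 0), c(0, 1)), 1)[[1]]
    expect_equal(sum(computeMismatch(c(b, 1 - b), d)), 0)
  }
})

test_that("mismatch corruption applies one scalar noise draw and silencing", {
  expect_equal(corruptMismatch(c(0.4, -0.4), beta = 0, xi = 3)$chiNoisy,
               c(0.4, -0.4))
  expect_equal(corruptMismatch(c(1, -1), beta = 2, xi = 0.5)$chiNoisy,
               c(2, -2))
  expect_equal(corruptMismatch(c(1, -1), beta = 2, silencingFactor = 0,
                               xi = 0.5)$chiNoisy, c(0, 0))
  expect_equal(corruptMismatch(c(0.8, -0.8), beta = 1, silencingFactor = 0.22,
                               xi = -0.3)$chiNoisy, 0.22 * c(0.8, -0.8) * 0.7)
})

test_that("belief update clips, renormalises, and matches hand arithmetic", {
  expect_equal(updateBelief(c(0.4, 0.6), c(0.5, -0.5), zeta = 0), c(0.4, 0.6))
  # best-fit switching rate from belief (0,1) under maximal mismatch
  expect_equal(updateBelief(c(0, 1), c(1, -1), zeta = 0.6858),
               c(0.6858, 0.3142), tolerance = 1e-12)
  # clip-then-normalise oracle on a pre-clip negative component
  b <- updateBelief(c(0.1, 0.9), c(-1, 1), zeta = 1)
  expect_equal(b, c(1e-9, 1.9) / (1e-9 + 1.9))
  # property: valid probability pair for random updates
  set.seed(4)
  for (i in 1:2000) {
    b0 <- runif(1); b0 <- c(b0, 1 - b0)
    chi <- corruptMismatch(computeMismatch(b0, sample(list(c(1, 0), c(0, 1)), 1)[[1]]),
                           beta = runif(1, 0, 4))$chiNoisy
    b1 <- updateBelief(b0, chi, zeta = runif(1, 0, 2))
    expect_true(all(b1 > 0))
    expect_equal(sum(b1), 1, tolerance = 1e-12)
  }
})

test_that("assumed block follows the larger belief with sticky ties", {
  expect_identical(assumedBlock(c(0.71, 0.29)), "VISUAL")
  expect_identical(assumedBlock(c(0.49, 0.51)), "ODOUR")
  expect_identical(assumedBlock(c(0.5, 0.5), previous = "ODOUR"), "ODOUR")
  expect_identical(assumedBlock(c(0.5, 0.5), previous = "VISUAL"), "VISUAL")
})

test_that("Q-tables are frozen in the belief agent's test phase", {
  tr <- runAgent(beliefAgentParams(), nSteps = 10000, phase = "train", seed = 6)
  te <- runAgent(beliefAgentParams(), nSteps = 5000, phase = "test",
                 state = tr$state, seed = 7)
  expect_identical(te$state$q, tr$state$q)
  expect_warning(
    runAgent(beliefAgentParams(), nSteps = 500, phase = "test",
             state = tr$state, seed = 8, alphaTest = 0.1),
    "test phase")
})

test_that("deterministic belief limit gives one-shot switches every time", {
  p <- beliefAgentParams(zeta = 1, beta = 0, epsilon = 0, epsilonPrime = 0)
  sim <- simulateExperiment(p, 20000, 8000, seed = 10)
  s <- summarizeTransitions(sim$log)
  ov <- s$transitions[s$transitions$direction == "odour_to_visual", ]
  expect_gt(nrow(ov), 20)
  expect_true(all(ov$isOneShot))
  # trace: belief flips within a single update at the transition
  expect_true(all(abs(sim$trace$chi_noisy_1[sim$trace$first_of_block]) > 0.99))
})

test_that("zeta = 0 freezes the belief and behavioural switching", {
  p <- beliefAgentParams(zeta = 0)
  sim <- simulateExperiment(p, 20000, 5000,
                            envCfg = envConfig(maxBlockTrials = 200), seed = 2)
  expect_equal(diff(range(sim$trace$p_visual)), 0)
  tr <- trialTable(sim$log)
  capped <- unique(tr$block_type[tr$block_cap_hit])
  expect_length(capped, 1)  # exactly one block type can never be solved
  s <- suppressWarnings(summarizeTransitions(sim$log))
  into <- s$transitions[s$transitions$direction ==
    (if (capped == "VISUAL") "odour_to_visual" else "visual_to_odour"), ]
  expect_true(all(!into$converged))
})

test_that("mean trials-to-switch decreases with the belief switching rate", {
  medTts <- function(zeta, seed) {
    p <- beliefAgentParams(zeta = zeta)
    sim <- simulateExperiment(p, 30000, 25000,
                              envCfg = envConfig(maxBlockTrials = 150),
                              seed = seed)
    s <- suppressWarnings(summarizeTransitions(sim$log))
    tt <- s$transitions
    tt <- tt[tt$direction == "odour_to_visual" & !tt$isFluke, ]
    mean(tt$trialsToSwitch)
  }
  grid <- c(0.2, 0.4, 0.7, 1.0)
  m <- vapply(seq_along(grid), function(i) medTts(grid[i], 40 + i), numeric(1))
  # non-increasing within Monte-Carlo slack
  expect_true(all(diff(m) < 1.0))
  expect_lt(m[4], m[1])
})

test_that("basic SARSA converges to the greedy-optimal visual policy", {
  # freeze the session in its first visual block: a strict > 1.0 accuracy
  # criterion can never be met, so no block switch occurs
  sim <- runAgent(basicAgentParams(epsilon = 0.05, alpha = 0.1),
                  nSteps = 400, phase = "train",
                  envCfg = envConfig(blockAccuracyThreshold = 1,
                                     maxBlockTrials = 10000), seed = 13)
  q <- matrix(sim$state$q[1:8], nrow = 4, byrow = TRUE,
              dimnames = list(TASK_CUES[1:4], TASK_ACTIONS))
  expect_gt(q["VISUAL_1", "LICK"], q["VISUAL_1", "NO_LICK"])
  expect_gt(q["VISUAL_2", "NO_LICK"], q["VISUAL_2", "LICK"])
  tr <- trialTable(sim$log)
  late <- tr[tr$trial_in_block >= 150, ]
  expect_gt(mean(late$relevant_correct), 0.9)
})
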