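test_that("lick-probability curves match a counting oracle", {
  # two blocks, deterministic licks: p(lick|VISUAL_1) = 1 wherever defined
  n <- 30
  tt <- handTrialTable(
    blockType = rep(c("ODOUR", "VISUAL"), each = n),
    finalCue = c(rep(c("ODOUR_1", "ODOUR_2"), n / 2), rep("VISUAL_1", n)),
    lickedFinal = c(rep(c(TRUE, FALSE), n / 2), rep(TRUE, n)))
  crv <- lickProbabilityCurve(tt, window = 5)
  ag <- aggregateCurve(crv)
  v1 <- ag$prob["odour_to_visual", "VISUAL_1", as.character(0:5)]
  expect_true(all(v1 == 1))
  # odour cues before the transition: alternate lick pattern -> exact counts
  expect_equal(unname(ag$prob["odour_to_visual", "ODOUR_1", as.character(-2)]), 1)
  expect_equal(unname(ag$count["odour_to_visual", "ODOUR_1", as.character(-2)]), 1)

  # fractional probability: 2 licks in 4 transitions at one position
  tt2 <- do.call(rbind, lapply(1:4, function(k) {
    h <- handTrialTable(blockType = rep(c("ODOUR", "VISUAL"), each = 3),
                        finalCue = c(rep("ODOUR_1", 3), rep("VISUAL_1", 3)),
                        lickedFinal = c(rep(TRUE, 3), k <= 2, TRUE, TRUE))
    h$block_index <- h$block_index + (k - 1) * 2
    h
  }))
  tt2$trial <- seq_len(nrow(tt2)) - 1L
  crv2 <- lickProbabilityCurve(tt2, window = 2)
  ag2 <- aggregateCurve(crv2)
  expect_equal(unname(ag2$prob["odour_to_visual", "VISUAL_1", "0"]), 0.5)
  expect_equal(unname(ag2$count["odour_to_visual", "VISUAL_1", "0"]), 4)
})

test_that("positions where a cue cannot occur are missing, not zero", {
  tt <- handTrialTable(blockType = rep(c("ODOUR", "VISUAL"), each = 10),
                       finalCue = c(rep("ODOUR_1", 10), rep("VISUAL_1", 10)),
                       lickedFinal = c(rep(TRUE, 10), rep(TRUE, 10)))
  ag <- aggregateCurve(lickProbabilityCurve(tt, window = 3))
  # VISUAL_2 never shown: all its cells are NA with zero count
  expect_true(all(is.na(ag$prob["odour_to_visual", "VISUAL_2", ])))
  expect_true(all(ag$count["odour_to_visual", "VISUAL_2", ] == 0))
})

test_that("curve RMSE has metric-like properties and honours missingness", {
  sim <- simulateExperiment(beliefAgentParams(), 20000, 15000, seed = 51)
  crv <- lickProbabilityCurve(sim$log, window = 8)
  expect_equal(curveRmse(crv, crv), 0)
  agA <- aggregateCurve(crv)
  agB <- agA
  mask <- !is.na(agB$prob)
  agB$prob[mask] <- pmin(1, agA$prob[mask] + 0.1)
  # constant offset of 0.1 on every defined cell (where headroom exists)
  agC <- agA; agC$prob[mask] <- agA$prob[mask] + 0.1
  expect_equal(curveRmse(agA, agC), 0.1)
  expect_equal(curveRmse(agC, agA), 0.1)  # symmetry
  # masked-mean oracle: knocking out one cell changes the RMSE accordingly
  agD <- agA
  def <- which(agD$count > 0)
  agD$count[def[1]] <- 0; agD$prob[def[1]] <- NA
  m2 <- agA$count > 0 & agD$count > 0
  expect_equal(curveRmse(agA, agD), 0)
  expect_error(curveRmse(agA, list(prob = agA$prob * NA,
                                   count = agA$count * 0)),
               "no overlapping")
})

test_that("a single-candidate grid is returned as the best fit", {
  sim <- simulateExperiment(beliefAgentParams(), 20000, 15000, seed = 52)
  crv <- lickProbabilityCurve(sim$log, window = 8)
  cfg <- fitConfig(nSteps = 2e4,
                   grid = list(zeta = 0.6858, beta = 1.997,
                               epsilon = 0.049, epsilonPrime = 0.280),
                   seeds = data.frame(seed = 61, variant = "V1"),
                   localOptStarts = 0, nFolds = 2)
  fit <- fitModel(crv, "belief", cfg)
  expect_equal(unname(fit$bestParams["zeta"]), 0.6858)
  expect_equal(unname(fit$bestParams["epsilonPrime"]), 0.280)
  expect_length(fit$perFoldRmseTest, 2)
  expect_true(all(fit$perFoldRmseTest >= 0))
})

test_that("fitting is reproducible for identical configurations", {
  sim <- simulateExperiment(beliefAgentParams(), 20000, 15000, seed = 53)
  crv <- lickProbabilityCurve(sim$log, window = 8)
  cfg <- fitConfig(nSteps = 2e4,
                   grid = list(zeta = c(0.4, 0.8), beta = c(1, 3),
                               epsilon = 0.05, epsilonPrime = 0.3),
                   seeds = data.frame(seed = 71:72, variant = c("V1", "V2")),
                   localOptStarts = 1, localMaxit = 10, nFolds = 2)
  f1 <- fitModel(crv, "belief", cfg)
  f2 <- fitModel(crv, "belief", cfg)
  expect_identical(f1$bestParams, f2$bestParams)
  expect_identical(f1$perFoldRmseTest, f2$perFoldRmseTest)
})

test_that("silencing-factor fitting leaves the base parameters untouched", {
  base <- beliefAgentParams()
  silenced <- base
  silenced$silencingFactorVisual <- 0.3
  dat <- simulateExperiment(silenced, 30000, 30000, seed = 54)
  crv <- lickProbabilityCurve(dat$log, window = 10)
  cfg <- fitConfig(nSteps = 3e4,
                   grid = list(factorVisual = c(0.2, 0.3, 0.6, 1),
                               factorOdour = c(0.5, 1)),
                   seeds = data.frame(seed = 81, variant = "V1"),
                   localMaxit = 0)
  fit <- fitSilencingFactors(crv, base, cfg)
  expect_identical(fit$baseParams, base)
  expect_true(fit$factorVisual >= 0 && fit$factorVisual <= 1)
  expect_true(fit$factorOdour >= 0 && fit$factorOdour <= 1)
})

test_that("recovered switching-rate error shrinks with more behavioural data", {
  fitOnce <- function(nTest, rep) {
    dat <- simulateExperiment(beliefAgentParams(), 30000, nTest,
                              seed = 500 + rep)
    crv <- lickProbabilityCurve(dat$log, window = 10)
    cfg <- fitConfig(nSteps = 6e4,
                     grid = list(zeta = seq(0.3, 1, by = 0.1), beta = 2,
                                 epsilon = 0.049, epsilonPrime = 0.28),
                     seeds = data.frame(seed = 600 + rep * 3 + 1:2,
                                        variant = "V1"),
                     localOptStarts = 0, localMaxit = 0, nFolds = 2,
                     refineSteps = 2e5, shortlist = 6)
    abs(fitModel(crv, "belief", cfg)$bestParams[["zeta"]] - 0.6858)
  }
  errSmall <- mean(vapply(1:3, function(r) fitOnce(8000, r), numeric(1)))
  errLarge <- mean(vapply(1:3, function(r) fitOnce(60000, r), numeric(1)))
  # monotone in expectation; generous Monte-Carlo slack for 3 replicates
  expect_lte(errLarge, errSmall + 0.05)
})

test_that("config and fit-result JSON round-trips preserve the fields", {
  cfgFile <- tempfile(fileext = ".json")
  writeEnvConfigJson(envConfig(pIrrelevantVisual = 0.6, transitionVariant = "V2",
                               maxBlockTrials = 123), cfgFile)
  cfg2 <- readEnvConfigJson(cfgFile)
  expect_equal(cfg2$pIrrelevantVisual, 0.6)
  expect_identical(cfg2$transitionVariant, "V2")
  expect_identical(cfg2$maxBlockTrials, 123L)

  sim <- simulateExperiment(beliefAgentParams(), 20000, 15000, seed = 55)
  crv <- lickProbabilityCurve(sim$log, window = 8)
  fit <- fitModel(crv, "belief",
                  fitConfig(nSteps = 2e4,
                            grid = list(zeta = c(0.5, 0.9), beta = 2,
                                        epsilon = 0.05, epsilonPrime = 0.3),
                            seeds = data.frame(seed = 66, variant = "V1"),
                            localOptStarts = 0, localMaxit = 0, nFolds = 2))
  fitFile <- tempfile(fileext = ".json")
  writeFitResultJson(fit, fitFile)
  back <- jsonlite::read_json(fitFile, simplifyVector = TRUE)
  expect_identical(back$model, "belief")
  expect_equal(back$fitted_parameters$zeta, unname(fit$bestParams["zeta"]))
  expect_equal(back$rmse_test_mean, fit$rmseMeanTest)
})
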