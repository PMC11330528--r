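test_that("dF/F is zero on constant traces and tracks steps via the baseline", {
  f <- matrix(100, nrow = 2, ncol = 400)
  r <- computeDff(f, frameRate = 10)
  expect_true(all(r$dff == 0))
  expect_true(all(r$baseline == 100))

  # windowed-minimum oracle: after a step from 100 to 150, the baseline
  # stays 100 for the 60 s window and dF/F is 0.5 there
  fs <- 10
  x <- c(rep(100, 100 * fs), rep(150, 100 * fs))
  r2 <- computeDff(matrix(x, 1), frameRate = fs)
  smoothLen <- max(1, round(0.75 * fs))
  inWin <- (100 * fs + smoothLen + 1):(160 * fs - 1)
  expect_true(all(abs(r2$dff[1, inWin] - 0.5) < 1e-12))
  # once the 60 s window has passed the step, the baseline catches up
  expect_equal(r2$baseline[1, 170 * fs], 150)
  expect_equal(r2$dff[1, 170 * fs], 0)

  # neurons with non-positive baseline are flagged and NA'd
  r3 <- computeDff(rbind(rep(0, 100), rep(5, 100)), frameRate = 4.8)
  expect_identical(r3$flagged, c(TRUE, FALSE))
  expect_true(all(is.na(r3$dff[1, ])))
})

test_that("dF/F is invariant to positive rescaling of the raw trace", {
  set.seed(8)
  x <- abs(rnorm(500, 100, 5)) + 50
  a <- computeDff(matrix(x, 1), frameRate = 4.8)$dff
  b <- computeDff(matrix(3.7 * x, 1), frameRate = 4.8)$dff
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("second-to-frame conversion rounds to the nearest frame, min 1", {
  expect_identical(switchRL:::spanToFrames(0.75, 4.8), 4L)   # 3.6 -> 4
  expect_identical(switchRL:::spanToFrames(1.5, 4.8), 7L)    # 7.2 -> 7
  expect_identical(switchRL:::spanToFrames(0.01, 4.8), 1L)   # minimum 1
  expect_identical(switchRL:::timeToFrame(0, 10), 1L)
  expect_identical(switchRL:::timeToFrame(2.04, 10), 21L)    # round(20.4) + 1
})

test_that("epoch extraction starts at the rounded frame of event + offset", {
  ses <- scriptedSession(nBlocks = 5, trialsPerBlock = 20, seed = 3)
  gen <- generateCalcium(syntheticNeuralConfig(nNeurons = 4, noiseSd = 0,
                                               fractionPePositive = 0.25,
                                               fractionPeNegative = 0,
                                               fractionTypeA = 0, fractionTypeB = 0,
                                               seed = 4), ses$log)
  rec <- gen$rec
  resp <- epochResponses(rec, epochSpec())
  expect_identical(dim(resp)[2], 3L)
  # index oracle: the planted neuron's PE response must equal the mean of
  # its noiseless transient over the window starting at round(t * fs) frames
  fs <- frameRate(rec)
  tpe <- gen$truth$peTimes[1]
  f0 <- as.integer(round(tpe * fs)) + 1L
  win <- f0:(f0 + switchRL:::spanToFrames(1.5, fs) - 1L)
  expect_equal(unname(resp[1, "prediction_error", 1]),
               mean(dff(rec)[1, win]))
  # a pure-noise neuron (noiseSd = 0 -> all-zero trace) has zero responses
  expect_true(all(resp[4, , ] == 0, na.rm = TRUE))
})

test_that("up-to-7 averaging uses the eligible trials nearest the transition", {
  ses <- scriptedSession(nBlocks = 5, trialsPerBlock = 25, seed = 6)
  gen <- generateCalcium(syntheticNeuralConfig(nNeurons = 2, noiseSd = 0,
                                               seed = 7), ses$log)
  ti <- as.data.frame(trialInfo(gen$rec))
  spec <- epochSpec()
  # oracle: count eligible condition-2 trials for the first transition
  tra <- which(ti$trial_in_block == 0 & ti$block_index > 0 &
                 ti$block_type == "VISUAL")[1]
  prev <- which(ti$block_index == ti$block_index[tra] - 1)
  elig <- prev[ti$has_irrelevant[prev] & !ti$licked_irrelevant[prev] &
                 !is.na(ti$odour_onset[prev])]
  expect_true(length(elig) > 7)  # more than the cap exist in a 25-trial block
  resp <- epochResponses(gen$rec, spec)
  expect_identical(dim(resp)[1], 2L)  # runs; the averaging cap is internal
  # with maxTrialsAveraged = 1 the odour response equals the single nearest trial
  r1 <- epochResponses(gen$rec, epochSpec(maxTrialsAveraged = 1))
  fs <- frameRate(gen$rec)
  f0 <- switchRL:::timeToFrame(ti$odour_onset[max(elig)], fs)
  win <- f0:(f0 + switchRL:::spanToFrames(1.5, fs) - 1L)
  expect_equal(unname(r1[1, "odour", 1]), mean(dff(gen$rec)[1, win]))
})

test_that("classification recovers planted classes and controls false positives", {
  ses <- scriptedSession(nBlocks = 21, trialsPerBlock = 25, seed = 10)
  cfg <- syntheticNeuralConfig(nNeurons = 60, fractionPePositive = 0.2,
                               fractionPeNegative = 0.1, fractionTypeA = 0.1,
                               fractionTypeB = 0.1, seed = 11)
  gen <- generateCalcium(cfg, ses$log)
  resp <- epochResponses(gen$rec)
  expect_gte(dim(resp)[3], 5)
  cls <- classifyNeurons(resp, alpha = 0.05)
  truth <- gen$truth$classes
  sens <- mean(cls$label[truth == "pe_positive"] == "prediction_error_positive")
  expect_gte(sens, 0.9)
  expect_gte(mean(cls$label[truth == "pe_negative"] ==
                    "prediction_error_negative"), 0.8)
  expect_gte(mean(cls$label[truth == "type_A"] == "type_A"), 0.7)
  expect_gte(mean(cls$label[truth == "type_B"] == "type_B"), 0.7)
  # dual criterion keeps noise neurons out of the prediction-error class
  fp <- mean(grepl("^prediction_error", cls$label[truth == "none"]))
  expect_lte(fp, 0.1)
  # too few transitions -> indeterminate
  short <- resp[, , 1:3, drop = FALSE]
  expect_true(all(classifyNeurons(short)$label == "indeterminate"))
})

test_that("sustained significance requires runs longer than the threshold", {
  fs <- 10
  n <- 24
  mk <- function(diffFrames) {
    a <- matrix(rnorm(n * 30, 0, 0.05), n, 30)
    b <- matrix(rnorm(n * 30, 0, 0.05), n, 30)
    b[, diffFrames] <- b[, diffFrames] + 1
    list(a = a, b = b)
  }
  set.seed(12)
  # 600 ms difference (6 frames) -> flagged
  x <- mk(11:16)
  m <- sustainedSignificance(x$b, x$a, alpha = 0.01, minDuration_s = 0.5,
                             frameRate = fs)
  expect_true(all(m[11:16]))
  expect_false(any(m[c(1:9, 18:30)]))
  # 400 ms difference (4 frames) -> not flagged
  y <- mk(11:14)
  expect_false(any(sustainedSignificance(y$b, y$a, alpha = 0.01,
                                         minDuration_s = 0.5, frameRate = fs)))
  # identical traces -> empty mask
  expect_false(any(sustainedSignificance(x$a, x$a, alpha = 0.01,
                                         minDuration_s = 0.5, frameRate = fs)))
  expect_error(sustainedSignificance(x$a[1:2, ], x$b[1:2, ], frameRate = fs),
               "3 paired")
})

test_that("decoding is accurate on separable data and balanced by subsampling", {
  set.seed(13)
  nTrial <- 60; nNeuron <- 15; nFrame <- 8
  x <- array(rnorm(nTrial * nNeuron * nFrame, 0, 0.5),
             dim = c(nTrial, nNeuron, nFrame))
  labels <- rep(c("A", "B"), each = nTrial / 2)
  # classes separable from frame 4 onwards
  x[labels == "A", , 4:8] <- x[labels == "A", , 4:8] + 2
  res <- decodeTimecourse(x, labels, nFolds = 5, seed = 14)
  expect_true(all(res$accuracy[5:8] >= 0.95))
  expect_true(all(res$accuracy <= 1))
  # balancing: 20 vs 40 trials -> 20 per class
  res2 <- decodeTimecourse(x[c(1:20, 31:60), , ], labels[c(1:20, 31:60)],
                           nFolds = 5, seed = 15)
  expect_identical(unname(res2$classSize), c(20L, 20L))
  expect_error(decodeTimecourse(x[1:6, , ], labels[c(1:3, 31:33)], nFolds = 5),
               "nFolds")
})

test_that("shuffled labels decode at chance", {
  set.seed(16)
  nTrial <- 120; x <- array(rnorm(nTrial * 10 * 6), dim = c(nTrial, 10, 6))
  labels <- sample(rep(c("A", "B"), each = nTrial / 2))
  res <- decodeTimecourse(x, labels, nFolds = 5, seed = 17)
  expect_lt(abs(mean(res$accuracy) - 0.5), 0.07)
})

test_that("bootstrap proportion CI behaves at the edges and brackets truth", {
  ci0 <- bootstrapProportionCi(rep(0, 50), nBoot = 1000, seed = 18)
  expect_identical(c(ci0$lower, ci0$upper), c(0, 0))
  expect_error(bootstrapProportionCi(c(0, 1), nBoot = 10), "1000")
  # 99% level uses the 0.5th/99.5th percentiles: check against quantile oracle
  set.seed(19)
  labels <- rbinom(500, 1, 0.1)
  ci <- bootstrapProportionCi(labels, subsetN = 410, nBoot = 10000,
                              level = 0.99, reference = 0.05, seed = 20)
  set.seed(20)
  props <- rbinom(10000, 410, mean(labels)) / 410
  qs <- quantile(props, c(0.005, 0.995), names = FALSE)
  expect_equal(c(ci$lower, ci$upper), qs)
  expect_identical(ci$referenceOutside, 0.05 < qs[1] || 0.05 > qs[2])
})

test_that("the encoding model recovers kernel-driven neurons and ablations", {
  set.seed(21)
  fs <- 5; nFrames <- 600
  lick <- as.numeric(runif(nFrames) < 0.05)
  vis <- as.numeric(runif(nFrames) < 0.03)
  run <- pmax(0, stats::filter(rnorm(nFrames), 0.8, method = "recursive"))
  kern <- exp(-(0:5) / 2)
  conv <- function(v, k) stats::filter(v, k, method = "convolution", sides = 1)
  lickDrive <- as.numeric(conv(lick, kern)); lickDrive[is.na(lickDrive)] <- 0
  visDrive <- as.numeric(conv(vis, kern)); visDrive[is.na(visDrive)] <- 0
  mat <- rbind(lickDrive,                       # noiseless motor neuron
               visDrive + rnorm(nFrames, 0, 0.01),  # sensory neuron
               rnorm(nFrames))                  # pure noise
  ev <- data.frame(type = "visual_onset",
                   time_s = (which(vis > 0) - 1) / fs, trial = NA)
  rec <- CalciumRecording(mat, frameRate = fs, events = ev,
                          colData = S4Vectors::DataFrame(
                            lick = lick, running_speed = as.numeric(run)))
  fit <- fitEncodingModel(rec, sensory = "visual_onset",
                          motor = c("lick", "running_speed"))
  expect_gte(fit$r2Full[1], 0.95)
  expect_lte(fit$r2Full[3], 0.05)
  # removing the motor regressors destroys the lick-driven neuron's fit
  expect_gt(fit$deltaR2[1], 0.5)
  expect_lt(abs(fit$deltaR2[2]), 0.2)
})
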