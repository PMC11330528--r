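#' Synthetic-calcium configuration
#'
#' Planted neuron classes are defined by which task moments they respond to
#' with an exponential-decay transient (single-exponential kernel, GCaMP7f
#' -like default tau = 0.7 s), on top of i.i.d. Gaussian frame noise:
#' * `pe_positive`: responds at the expected-odour omission moment of the
#'   first post-transition trial only (default; see `peFirstTrialOnly`);
#' * `pe_negative`: responds at odour deliveries *and* at the matched
#'   no-odour moments, but not to the omission (so its prediction-error
#'   response is the smallest of the three epochs);
#' * `type_A`: responds at odour deliveries only;
#' * `type_B`: responds at the no-odour moments only;
#' * remaining neurons are pure noise.
#'
#' @param nNeurons total neurons.
#' @param fractionPePositive,fractionPeNegative,fractionTypeA,fractionTypeB
#'   class fractions (sum <= 1); the default 9% positive prediction-error
#'   fraction mirrors the reported ACC proportion.
#' @param responseAmplitude transient peak in dF/F units.
#' @param noiseSd per-frame Gaussian noise SD in dF/F units (amplitude 3x
#'   noise SD by default).
#' @param kernelTau_s transient decay constant in seconds.
#' @param frameRate acquisition rate in Hz (default 4.8, a typical
#'   volumetric two-photon rate).
#' @param peFirstTrialOnly if TRUE (default) the planted prediction-error
#'   response occurs only on the first post-transition trial.
#' @param seed integer seed.
#' @return list of class `"SyntheticNeuralConfig"`.
#' @export
syntheticNeuralConfig <- function(nNeurons = 200L, fractionPePositive = 0.09,
                                  fractionPeNegative = 0.03,
                                  fractionTypeA = 0.10, fractionTypeB = 0.05,
                                  responseAmplitude = 0.6, noiseSd = 0.2,
                                  kernelTau_s = 0.7, frameRate = 4.8,
                                  peFirstTrialOnly = TRUE, seed = 1L) {
  fr <- c(fractionPePositive, fractionPeNegative, fractionTypeA, fractionTypeB)
  stopifnot(all(fr >= 0), sum(fr) <= 1, noiseSd >= 0, kernelTau_s > 0,
            frameRate > 0, nNeurons >= 1)
  structure(list(nNeurons = as.integer(nNeurons),
                 fractionPePositive = fractionPePositive,
                 fractionPeNegative = fractionPeNegative,
                 fractionTypeA = fractionTypeA, fractionTypeB = fractionTypeB,
                 responseAmplitude = responseAmplitude, noiseSd = noiseSd,
                 kernelTau_s = kernelTau_s, frameRate = frameRate,
                 peFirstTrialOnly = isTRUE(peFirstTrialOnly),
                 seed = as.integer(seed)),
            class = "SyntheticNeuralConfig")
}

# fixed trial timing used to lay a session log onto a timeline (seconds)
SYNTH_TIMING <- list(lead = 0.5, stim = 1.8, visOdourGap = 1.8,
                     postVisual = 4.0, postOdour = 3.0, lickDelay = 0.7)

sessionTimeline <- function(tr) {
  tm <- SYNTH_TIMING
  n <- nrow(tr)
  tStart <- tEnd <- visOn <- visOff <- odOn <- rep(NA_real_, n)
  t <- 1.0
  for (i in seq_len(n)) {
    tStart[i] <- t
    if (tr$block_type[i] == "VISUAL") {
      visOn[i] <- t + tm$lead; visOff[i] <- visOn[i] + tm$stim
      tEnd[i] <- visOff[i] + tm$postVisual
    } else {
      if (tr$has_irrelevant[i]) {
        visOn[i] <- t + tm$lead; visOff[i] <- visOn[i] + tm$stim
        odOn[i] <- visOff[i] + tm$visOdourGap
      } else {
        odOn[i] <- t + tm$lead
      }
      tEnd[i] <- odOn[i] + tm$stim + tm$postOdour
    }
    t <- tEnd[i]
  }
  data.frame(t_start = tStart, t_end = tEnd, visual_onset = visOn,
             visual_offset = visOff, odour_onset = odOn)
}

addTransients <- function(mat, neuronRows, times_s, amplitude, tau_s, fs) {
  if (!length(neuronRows) || !length(times_s)) return(mat)
  nFrames <- ncol(mat)
  kLen <- ceiling(5 * tau_s * fs)
  kernel <- amplitude * exp(-(0:kLen) / (tau_s * fs))
  template <- numeric(nFrames)
  for (t0 in timeToFrame(times_s, fs)) {
    idx <- t0:min(t0 + kLen, nFrames)
    if (t0 <= nFrames) template[idx] <- template[idx] + kernel[seq_along(idx)]
  }
  mat[neuronRows, ] <- mat[neuronRows, , drop = FALSE] +
    rep(template, each = length(neuronRows))
  mat
}

#' Generate a synthetic calcium recording from a behavioural session
#'
#' Lays the session's trials onto a timeline (fixed stimulus and intertrial
#' durations), builds the task-event table, and plants class-defining
#' transient responses plus Gaussian noise (see [syntheticNeuralConfig()]).
#'
#' @param cfg a [syntheticNeuralConfig()].
#' @param log a [SessionLog] containing at least one odour-to-visual
#'   transition.
#' @return list with `rec` (a [CalciumRecording]; `rowData(rec)$true_class`
#'   holds the planted labels) and `truth` (labels plus the per-class event
#'   times).
#' @export
generateCalcium <- function(cfg = syntheticNeuralConfig(), log) {
  stopifnot(inherits(cfg, "SyntheticNeuralConfig"), is(log, "SessionLog"))
  tr <- trialTable(log)
  if (!any(tr$trial_in_block == 0 & tr$block_index > 0 &
             tr$block_type == "VISUAL"))
    stop("log contains no odour-to-visual transition")
  set.seed(cfg$seed)
  fs <- cfg$frameRate
  tl <- sessionTimeline(tr)
  nFrames <- ceiling((max(tl$t_end) + 2) * fs)

  # class-defining event times
  transRows <- which(tr$trial_in_block == 0 & tr$block_index > 0 &
                       tr$block_type == "VISUAL")
  peRows <- transRows[!tr$licked_final[transRows]]
  peTimes <- tl$visual_offset[peRows] + 2.0
  if (!cfg$peFirstTrialOnly) {
    extra <- setdiff(c(transRows + 1L, transRows + 2L), peRows)
    extra <- extra[extra <= nrow(tr) & tr$block_type[extra] == "VISUAL"]
    peTimes <- sort(c(peTimes, tl$visual_offset[extra] + 2.0))
  }
  odourTimes <- tl$odour_onset[!is.na(tl$odour_onset)]
  noOdourRows <- which(tr$block_type == "VISUAL" & tr$final_cue == "VISUAL_2" &
                         !tr$transition_phase)
  noOdourTimes <- tl$visual_offset[noOdourRows] + 2.0

  # class assignment (first the planted classes, the remainder pure noise)
  fracs <- c(pe_positive = cfg$fractionPePositive,
             pe_negative = cfg$fractionPeNegative,
             type_A = cfg$fractionTypeA, type_B = cfg$fractionTypeB)
  classes <- rep("none", cfg$nNeurons)
  cursor <- 0L
  for (nm in names(fracs)) {
    k <- round(fracs[[nm]] * cfg$nNeurons)
    if (k > 0 && cursor < cfg$nNeurons) {
      idx <- (cursor + 1L):min(cursor + k, cfg$nNeurons)
      classes[idx] <- nm
      cursor <- max(idx)
    }
  }

  mat <- matrix(if (cfg$noiseSd > 0) rnorm(cfg$nNeurons * nFrames, 0, cfg$noiseSd)
                else 0, nrow = cfg$nNeurons, ncol = nFrames)
  A <- cfg$responseAmplitude; tau <- cfg$kernelTau_s
  mat <- addTransients(mat, which(classes == "pe_positive"), peTimes, A, tau, fs)
  mat <- addTransients(mat, which(classes == "pe_negative"),
                       c(odourTimes, noOdourTimes), A, tau, fs)
  mat <- addTransients(mat, which(classes == "type_A"), odourTimes, A, tau, fs)
  mat <- addTransients(mat, which(classes == "type_B"), noOdourTimes, A, tau, fs)

  # event table and per-frame covariates
  lickTimes <- c(tl$visual_onset[tr$licked_final &
                                   tr$block_type == "VISUAL"] + SYNTH_TIMING$lickDelay,
                 tl$odour_onset[tr$licked_final &
                                  tr$block_type == "ODOUR"] + SYNTH_TIMING$lickDelay,
                 tl$visual_onset[tr$licked_irrelevant] + SYNTH_TIMING$lickDelay)
  lickTimes <- sort(lickTimes[!is.na(lickTimes)])
  rewardTimes <- c(tl$visual_onset[tr$licked_final & tr$final_cue == "VISUAL_1"],
                   tl$odour_onset[tr$licked_final & tr$final_cue == "ODOUR_1"])
  rewardTimes <- sort(rewardTimes[!is.na(rewardTimes)]) + SYNTH_TIMING$lickDelay + 0.1
  ev <- rbind(
    data.frame(type = "visual_onset", time_s = tl$visual_onset, trial = tr$trial),
    data.frame(type = "visual_offset", time_s = tl$visual_offset, trial = tr$trial),
    data.frame(type = "odour_onset", time_s = tl$odour_onset, trial = tr$trial),
    data.frame(type = "transition", time_s = tl$t_start, trial = tr$trial)[
      tr$trial_in_block == 0 & tr$block_index > 0, ],
    data.frame(type = "lick", time_s = lickTimes, trial = NA_integer_),
    data.frame(type = "reward", time_s = rewardTimes, trial = NA_integer_))
  ev <- ev[!is.na(ev$time_s), ]
  ev <- ev[order(ev$time_s), ]

  lickTrace <- numeric(nFrames)
  lickTrace[timeToFrame(lickTimes, fs)] <- 1
  running <- pmax(0, 4 + as.numeric(stats::filter(rnorm(nFrames), 0.9,
                                                  method = "recursive")))

  ti <- cbind(tr, tl)
  rec <- CalciumRecording(mat, frameRate = fs, events = ev, trialInfo = ti,
                          rowData = S4Vectors::DataFrame(true_class = classes),
                          colData = S4Vectors::DataFrame(
                            time_s = (seq_len(nFrames) - 1) / fs,
                            lick = lickTrace, running_speed = running))
  truth <- list(classes = classes, peTimes = peTimes, odourTimes = odourTimes,
                noOdourTimes = noOdourTimes, config = cfg)
  list(rec = rec, truth = truth)
}
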