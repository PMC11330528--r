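#' Epoch specification for prediction-error screening
#'
#' Defines the three response epochs used to screen for prediction-error
#' neurons around odour-to-visual block transitions:
#' 1. *odour prediction error*: starting `peOffset_s` (default 2.0 s, the
#'    typical visual-offset-to-odour delay) after the offset of the first
#'    visual stimulus of the new visual block, provided the animal did not
#'    lick to that stimulus;
#' 2. *odour*: aligned to odour onsets at the end of the preceding odour
#'    block, following a correctly ignored grating;
#' 3. *no odour predicted*: `peOffset_s` after the offsets of unrewarded
#'    visual stimuli later in the same visual block, excluding its final
#'    `excludeLastTrials` trials.
#' Conditions 2 and 3 average up to `maxTrialsAveraged` eligible trials per
#' transition (the trials nearest the transition). Responses are means over
#' a `window_s` (default 1.5 s) window.
#'
#' @param window_s epoch duration in seconds.
#' @param peOffset_s delay from visual offset to the expected-odour moment.
#' @param maxTrialsAveraged cap on trials averaged in conditions 2-3.
#' @param excludeLastTrials visual-block trials excluded at block end for
#'   condition 3 (default 10).
#' @param selectNearest if TRUE (default) the eligible trials nearest the
#'   transition are used when more than `maxTrialsAveraged` exist; FALSE
#'   samples them randomly.
#' @return list of class `"EpochSpec"`.
#' @export
epochSpec <- function(window_s = 1.5, peOffset_s = 2.0,
                      maxTrialsAveraged = 7L, excludeLastTrials = 10L,
                      selectNearest = TRUE) {
  stopifnot(window_s > 0, peOffset_s >= 0, maxTrialsAveraged >= 1)
  structure(list(window_s = window_s, peOffset_s = peOffset_s,
                 maxTrialsAveraged = as.integer(maxTrialsAveraged),
                 excludeLastTrials = as.integer(excludeLastTrials),
                 selectNearest = isTRUE(selectNearest)),
            class = "EpochSpec")
}

EPOCH_CONDITIONS <- c("prediction_error", "odour", "no_odour_predicted")

windowMean <- function(mat, startFrame, nFrames) {
  idx <- startFrame:(startFrame + nFrames - 1L)
  idx <- idx[idx >= 1L & idx <= ncol(mat)]
  if (!length(idx)) return(rep(NA_real_, nrow(mat)))
  rowMeans(mat[, idx, drop = FALSE])
}

#' Event-aligned epoch responses
#'
#' Extracts the per-neuron mean response in the three screening epochs for
#' every odour-to-visual block transition of a recording (see
#' [epochSpec()]). Transitions without an eligible prediction-error epoch or
#' without any eligible condition-2/3 trial are dropped.
#'
#' @param rec a [CalciumRecording] whose `trialInfo` carries the stimulus
#'   times (`visual_onset`, `visual_offset`, `odour_onset`) and outcome
#'   flags per trial.
#' @param spec an [epochSpec()].
#' @return numeric array `neuron x condition x transition` with dimnames;
#'   transitions that were dropped are absent. Attribute `"transitions"`
#'   gives the global trial index of the first trial of each kept
#'   transition.
#' @export
epochResponses <- function(rec, spec = epochSpec()) {
  ti <- as.data.frame(trialInfo(rec))
  if (!nrow(ti)) stop("recording has no trial annotation")
  fs <- frameRate(rec)
  mat <- dff(rec)
  win <- spanToFrames(spec$window_s, fs)

  transRows <- which(ti$trial_in_block == 0 & ti$block_index > 0 &
                       ti$block_type == "VISUAL")
  if (!length(transRows)) stop("recording contains no odour-to-visual transition")

  pickTrials <- function(idx, decreasing) {
    if (length(idx) <= spec$maxTrialsAveraged) return(idx)
    if (spec$selectNearest) {
      idx <- sort(idx, decreasing = decreasing)
      sort(idx[seq_len(spec$maxTrialsAveraged)])
    } else sort(sample(idx, spec$maxTrialsAveraged))
  }

  res <- list(); keptTrans <- integer()
  for (r in transRows) {
    bi <- ti$block_index[r]
    blk <- which(ti$block_index == bi)
    prevBlk <- which(ti$block_index == bi - 1L)

    # condition 1: first grating of the new block, not licked, odour omitted
    if (!isTRUE(!ti$licked_final[r]) || is.na(ti$visual_offset[r])) next
    peStart <- timeToFrame(ti$visual_offset[r] + spec$peOffset_s, fs)
    peResp <- windowMean(mat, peStart, win)

    # condition 2: odour onsets at the end of the preceding odour block,
    # following a correctly ignored grating
    odourIdx <- prevBlk[ti$has_irrelevant[prevBlk] &
                          !ti$licked_irrelevant[prevBlk] &
                          !is.na(ti$odour_onset[prevBlk])]
    odourIdx <- pickTrials(odourIdx, decreasing = TRUE)  # nearest = latest
    if (!length(odourIdx)) next

    # condition 3: unrewarded-grating offsets later in the visual block,
    # outside the transition period and the final trials of the block
    lastOk <- max(ti$trial_in_block[blk]) - spec$excludeLastTrials
    noOdourIdx <- blk[ti$final_cue[blk] == "VISUAL_2" &
                        !ti$transition_phase[blk] &
                        ti$trial_in_block[blk] <= lastOk &
                        !is.na(ti$visual_offset[blk])]
    noOdourIdx <- pickTrials(noOdourIdx, decreasing = FALSE)  # nearest = earliest
    if (!length(noOdourIdx)) next

    avgResp <- function(idx, times) {
      starts <- timeToFrame(times + 0, fs)
      rowMeans(vapply(starts, function(s0) windowMean(mat, s0, win),
                      numeric(nrow(mat))))
    }
    odourResp <- avgResp(odourIdx, ti$odour_onset[odourIdx])
    noOdourResp <- avgResp(noOdourIdx,
                           ti$visual_offset[noOdourIdx] + spec$peOffset_s)
    res[[length(res) + 1L]] <- cbind(peResp, odourResp, noOdourResp)
    keptTrans <- c(keptTrans, ti$trial[r])
  }
  if (!length(res)) stop("no transition passed the eligibility rules")
  out <- array(unlist(res),
               dim = c(nrow(mat), 3L, length(res)),
               dimnames = list(rownames(mat), EPOCH_CONDITIONS, NULL))
  attr(out, "transitions") <- keptTrans
  out
}

#' Classify prediction-error neurons
#'
#' Per neuron, two two-sided rank-sum tests across transitions compare the
#' prediction-error epoch responses with the odour and the
#' no-odour-predicted responses (sample size = number of transitions).
#' Neurons significant in *both* comparisons are prediction-error neurons,
#' signed positive/negative according to whether the prediction-error mean
#' is the largest/smallest of the three condition means (other sign patterns
#' are `prediction_error_other`). Neurons significant only against the odour
#' condition are Type A; only against the no-odour condition, Type B.
#'
#' @param responses array from [epochResponses()].
#' @param alpha two-sided significance level (default 0.05).
#' @param minTransitions minimum usable transitions per neuron; below it the
#'   neuron is labelled `"indeterminate"` (default 5).
#' @return data.frame of class `"NeuronClassification"`: `neuron`, `label`,
#'   `pOdour`, `pNoOdour`, and the three condition means.
#' @export
classifyNeurons <- function(responses, alpha = 0.05, minTransitions = 5L) {
  nN <- dim(responses)[1]
  out <- data.frame(neuron = dimnames(responses)[[1]] %||% seq_len(nN),
                    label = "none", pOdour = NA_real_, pNoOdour = NA_real_,
                    meanPe = NA_real_, meanOdour = NA_real_,
                    meanNoOdour = NA_real_)
  for (i in seq_len(nN)) {
    pe <- responses[i, 1, ]; od <- responses[i, 2, ]; no <- responses[i, 3, ]
    ok <- stats::complete.cases(cbind(pe, od, no))
    pe <- pe[ok]; od <- od[ok]; no <- no[ok]
    out$meanPe[i] <- mean(pe); out$meanOdour[i] <- mean(od)
    out$meanNoOdour[i] <- mean(no)
    if (sum(ok) < minTransitions) { out$label[i] <- "indeterminate"; next }
    p1 <- suppressWarnings(wilcox.test(pe, od, exact = FALSE)$p.value)
    p2 <- suppressWarnings(wilcox.test(pe, no, exact = FALSE)$p.value)
    out$pOdour[i] <- p1; out$pNoOdour[i] <- p2
    s1 <- p1 < alpha; s2 <- p2 < alpha
    out$label[i] <- if (s1 && s2) {
      m <- c(out$meanPe[i], out$meanOdour[i], out$meanNoOdour[i])
      if (which.max(m) == 1) "prediction_error_positive"
      else if (which.min(m) == 1) "prediction_error_negative"
      else "prediction_error_other"
    } else if (s1) "type_A" else if (s2) "type_B" else "none"
  }
  class(out) <- c("NeuronClassification", class(out))
  out
}

#' Sustained-significance mask
#'
#' Per-frame two-sided paired t-tests between two paired condition traces;
#' frames are flagged only within runs of consecutively significant frames
#' whose duration strictly exceeds `minDuration_s` (e.g. P < 0.01 for more
#' than 500 ms).
#'
#' @param tracesA,tracesB matrices `observation x frame` with matched rows
#'   (paired observations).
#' @param alpha per-frame significance level (default 0.01).
#' @param minDuration_s run-length threshold in seconds (default 0.5).
#' @param frameRate acquisition rate in Hz.
#' @return logical vector over frames.
#' @export
sustainedSignificance <- function(tracesA, tracesB, alpha = 0.01,
                                  minDuration_s = 0.5, frameRate) {
  stopifnot(identical(dim(tracesA), dim(tracesB)))
  if (nrow(tracesA) < 3) stop("need at least 3 paired observations")
  p <- vapply(seq_len(ncol(tracesA)), function(f) {
    d <- tracesA[, f] - tracesB[, f]
    if (sd(d) == 0) (if (all(d == 0)) 1.0 else 0.0)  # degenerate: no spread
    else t.test(tracesA[, f], tracesB[, f], paired = TRUE)$p.value
  }, numeric(1))
  sig <- p < alpha
  mask <- logical(length(sig))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / frameRate) > minDuration_s
  for (j in which(keep)) mask[starts[j]:ends[j]] <- TRUE
  mask
}
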