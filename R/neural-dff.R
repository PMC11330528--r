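#' Compute dF/F with a running-minimum baseline
#'
#' The raw trace of each neuron is smoothed with a causal moving average
#' (default 0.75 s), the baseline F0(t) is the minimum of the smoothed trace
#' over the preceding window (default 60 s, history-limited at the trace
#' start), and dF/F = (F - F0) / F0. Second-to-frame conversions round to
#' the nearest frame with a minimum of one frame. Neurons whose baseline
#' ever drops to or below zero are flagged for exclusion downstream (their
#' dF/F rows are NA).
#'
#' @param rawF neurons x frames matrix of raw fluorescence.
#' @param frameRate acquisition rate in Hz.
#' @param smoothWindow_s causal moving-average width in seconds.
#' @param baselineWindow_s running-minimum window in seconds.
#' @return list with `baseline` (F0 matrix), `dff` (matrix), and `flagged`
#'   (logical per neuron, TRUE when the baseline was non-positive somewhere).
#' @examples
#' f <- matrix(100, nrow = 1, ncol = 50)
#' computeDff(f, frameRate = 10)$dff[1, 1]  # 0
#' @export
computeDff <- function(rawF, frameRate, smoothWindow_s = 0.75,
                       baselineWindow_s = 60) {
  if (!is.numeric(frameRate) || frameRate <= 0)
    stop("frameRate must be positive")
  rawF <- as.matrix(rawF)
  k <- spanToFrames(smoothWindow_s, frameRate)
  w <- spanToFrames(baselineWindow_s, frameRate)
  baseline <- rawF
  for (i in seq_len(nrow(rawF)))
    baseline[i, ] <- cpp_running_min(cpp_causal_moving_average(rawF[i, ], k), w)
  flagged <- apply(baseline <= 0, 1, any)
  dffM <- (rawF - baseline) / baseline
  dffM[flagged, ] <- NA_real_
  list(baseline = baseline, dff = dffM, flagged = flagged)
}
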