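#' Align activity into a trial x neuron x frame array
#'
#' Cuts fixed-length windows of the dF/F matrix around a set of alignment
#' times (e.g. stimulus onsets), for use with [decodeTimecourse()].
#'
#' @param rec a [CalciumRecording].
#' @param times_s numeric alignment times in seconds (one per trial).
#' @param window_s numeric length-2 window around each time, default
#'   `c(-1, 3)` seconds.
#' @return numeric array `trial x neuron x frame`; attribute `"time_s"`
#'   holds the frame times relative to alignment.
#' @export
alignActivity <- function(rec, times_s, window_s = c(-1, 3)) {
  fs <- frameRate(rec)
  mat <- dff(rec)
  rel <- seq(round(window_s[1] * fs), round(window_s[2] * fs))
  out <- array(NA_real_, dim = c(length(times_s), nrow(mat), length(rel)))
  for (i in seq_along(times_s)) {
    idx <- timeToFrame(times_s[i], fs) + rel
    ok <- idx >= 1 & idx <= ncol(mat)
    out[i, , ok] <- mat[, idx[ok]]
  }
  attr(out, "time_s") <- rel / fs
  out
}

stratifiedFolds <- function(labels, nFolds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

#' Per-frame population decoding
#'
#' Trains a binary L2-regularised logistic-regression classifier on the
#' neuron-activity vector at each frame, under stratified k-fold
#' cross-validation. Classes are first balanced by randomly subsampling the
#' larger class. Accuracy is the mean over the held-out folds.
#'
#' @param x array `trial x neuron x frame` (see [alignActivity()]).
#' @param labels two-class factor/character/logical per trial.
#' @param nFolds folds for stratified cross-validation (default 5).
#' @param lambda ridge penalty passed to glmnet (default 1).
#' @param seed optional seed controlling the balancing subsample and fold
#'   assignment.
#' @return list of class `"DecodeResult"`: `accuracy` (per frame), `time_s`
#'   (if present on `x`), `nFolds`, `classSize` (per-class trial count after
#'   balancing).
#' @export
decodeTimecourse <- function(x, labels, nFolds = 5L, lambda = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ts <- attr(x, "time_s")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("exactly two classes are required")
  nPer <- min(table(labels))
  if (nPer < nFolds) stop("each class needs at least nFolds trials")
  keep <- unlist(lapply(classes, function(cl) {
    idx <- which(labels == cl)
    if (length(idx) > nPer) sample(idx, nPer) else idx
  }))
  x <- x[keep, , , drop = FALSE]
  y <- factor(labels[keep], levels = classes)
  fold <- stratifiedFolds(as.character(y), nFolds)

  nFrames <- dim(x)[3]
  acc <- numeric(nFrames)
  for (f in seq_len(nFrames)) {
    X <- x[, , f]
    ok <- stats::complete.cases(X)
    foldAcc <- vapply(seq_len(nFolds), function(k) {
      tr <- ok & fold != k
      te <- ok & fold == k
      if (sum(te) == 0 || length(unique(y[tr])) < 2) return(NA_real_)
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = 0, lambda = lambda)
      pred <- predict(fit, X[te, , drop = FALSE], type = "class")
      mean(pred == as.character(y[te]))
    }, numeric(1))
    acc[f] <- mean(foldAcc, na.rm = TRUE)
  }
  structure(list(accuracy = acc, time_s = ts,
                 nFolds = as.integer(nFolds),
                 classSize = setNames(rep(nPer, 2), classes)),
            class = "DecodeResult")
}
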