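#' Build a time-shifted event design matrix
#'
#' Each regressor is a per-frame event trace plus copies of itself shifted
#' in time by one frame each: sensory regressors span lags 0 to
#' `sensorySpan_s` (default 2 s) after the event, motor regressors
#' (licking, running) span `-motorPre_s` (default 0.5 s) before to
#' `motorPost_s` (default 2 s) after.
#'
#' @param traces named list of per-frame numeric traces (binary event trains
#'   or continuous covariates), all of the same length.
#' @param sensory,motor character vectors naming which traces receive the
#'   sensory / motor lag structure.
#' @param frameRate acquisition rate in Hz.
#' @param sensorySpan_s,motorPre_s,motorPost_s lag spans in seconds.
#' @return numeric design matrix `frames x lagged-regressors` with column
#'   names `<trace>.lag<k>`; attribute `"regressor"` maps columns to their
#'   source trace.
#' @export
buildDesignMatrix <- function(traces, sensory, motor, frameRate,
                              sensorySpan_s = 2, motorPre_s = 0.5,
                              motorPost_s = 2) {
  miss <- setdiff(c(sensory, motor), names(traces))
  if (length(miss)) stop("missing traces: ", paste(miss, collapse = ", "))
  n <- length(traces[[1]])
  shift <- function(v, k) {  # positive k delays the trace by k frames
    if (k >= 0) c(rep(0, k), v[seq_len(n - k)])
    else c(v[(1 - k):n], rep(0, -k))
  }
  cols <- list(); src <- character()
  for (nm in c(sensory, motor)) {
    lags <- if (nm %in% sensory) 0:spanToFrames(sensorySpan_s, frameRate)
            else -spanToFrames(motorPre_s, frameRate):spanToFrames(motorPost_s, frameRate)
    for (k in lags) {
      cols[[paste0(nm, ".lag", k)]] <- shift(traces[[nm]], k)
      src <- c(src, nm)
    }
  }
  X <- do.call(cbind, cols)
  attr(X, "regressor") <- src
  X
}

encodingLambdaGrid <- function() 10^seq(5, -2, length.out = 36)

cvRidgeR2 <- function(X, y, lambdas, nFolds) {
  n <- length(y)
  foldId <- cut(seq_len(n), breaks = nFolds, labels = FALSE)  # contiguous
  pred <- matrix(NA_real_, n, length(lambdas))
  for (k in seq_len(nFolds)) {
    tr <- foldId != k
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = 0,
                          lambda = lambdas)
    pred[!tr, ] <- predict(fit, X[!tr, , drop = FALSE], s = lambdas)
  }
  mse <- colMeans((pred - y)^2)
  best <- which.min(mse)
  r2 <- 1 - sum((pred[, best] - y)^2) / sum((y - mean(y))^2)
  list(r2 = r2, lambda = lambdas[best])
}

#' Ridge encoding model with time-shifted regressors
#'
#' Predicts each neuron's dF/F trace from a time-lagged design matrix of
#' task events and motor covariates by ridge regression, with the penalty
#' chosen per neuron from 36 log-spaced values between 1e-2 and 1e5 under
#' 5-fold cross-validation (contiguous frame folds). Reports the
#' cross-validated R-squared of the full model, of a reduced model without
#' the motor (running and licking) regressors, and their difference.
#'
#' @param rec a [CalciumRecording]; per-frame covariates named in `motor`
#'   are looked up in `colData(rec)`, point events in the event table
#'   (binarised at their frame).
#' @param sensory event types given sensory lag structure (default
#'   `c("visual_onset", "odour_onset")`).
#' @param motor covariates given motor lag structure (default
#'   `c("lick", "running_speed")`).
#' @param nFolds cross-validation folds (default 5).
#' @param lambdas ridge penalty grid (default 36 log-spaced values,
#'   1e-2..1e5).
#' @return data.frame of class `"EncodingFit"`: per neuron `r2Full`,
#'   `r2Reduced`, `deltaR2`, `lambdaFull`, `lambdaReduced`.
#' @export
fitEncodingModel <- function(rec, sensory = c("visual_onset", "odour_onset"),
                             motor = c("lick", "running_speed"),
                             nFolds = 5L, lambdas = encodingLambdaGrid()) {
  fs <- frameRate(rec)
  mat <- dff(rec)
  nFrames <- ncol(mat)
  ev <- as.data.frame(taskEvents(rec))
  cd <- as.data.frame(colData(rec))
  traceOf <- function(nm) {
    if (nm %in% colnames(cd)) return(as.numeric(cd[[nm]]))
    tt <- ev$time_s[ev$type == nm]
    if (!length(tt)) stop("no events or covariate named '", nm, "'")
    v <- numeric(nFrames)
    f <- timeToFrame(tt, fs)
    v[f[f <= nFrames]] <- 1
    v
  }
  traces <- setNames(lapply(c(sensory, motor), traceOf), c(sensory, motor))
  Xfull <- buildDesignMatrix(traces, sensory, motor, fs)
  Xred <- Xfull[, !(attr(Xfull, "regressor") %in% motor), drop = FALSE]

  lambdas <- sort(lambdas, decreasing = TRUE)
  out <- data.frame(neuron = rownames(mat), r2Full = NA_real_,
                    r2Reduced = NA_real_, deltaR2 = NA_real_,
                    lambdaFull = NA_real_, lambdaReduced = NA_real_)
  for (i in seq_len(nrow(mat))) {
    y <- mat[i, ]
    if (anyNA(y)) next
    full <- cvRidgeR2(Xfull, y, lambdas, nFolds)
    red <- cvRidgeR2(Xred, y, lambdas, nFolds)
    out$r2Full[i] <- full$r2; out$lambdaFull[i] <- full$lambda
    out$r2Reduced[i] <- red$r2; out$lambdaReduced[i] <- red$lambda
    out$deltaR2[i] <- full$r2 - red$r2
  }
  class(out) <- c("EncodingFit", class(out))
  out
}
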