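#' Behavioural d-prime
#'
#' `bd' = qnorm(H) - qnorm(F)`, the normal-quantile separation of the hit
#' rate and the false-alarm rate. Rates are clipped into
#' `[1/(2n), 1 - 1/(2n)]` so perfect rates stay finite.
#'
#' @param hitRate,faRate hit and false-alarm probabilities in \[0, 1\].
#' @param n trial count used for the clipping bound (>= 1).
#' @return list of class `"DprimeResult"`: `hitRate`, `faRate` (after
#'   clipping), `bdPrime`, `n`.
#' @examples
#' behaviouralDprime(0.841345, 0.158655, 100)$bdPrime  # ~2
#' @export
behaviouralDprime <- function(hitRate, faRate, n) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be a positive count")
  stopifnot(hitRate >= 0, hitRate <= 1, faRate >= 0, faRate <= 1)
  lo <- 1 / (2 * n)
  h <- min(max(hitRate, lo), 1 - lo)
  f <- min(max(faRate, lo), 1 - lo)
  structure(list(hitRate = h, faRate = f, bdPrime = qnorm(h) - qnorm(f),
                 n = as.integer(n)),
            class = "DprimeResult")
}

#' Switching speed of one block transition
#'
#' Number of trials that elapse before the first run of three consecutive
#' correct responses to the relevant stimuli begins. 0 marks a "fluke"
#' (correct response to the very first relevant stimulus of the new block,
#' before any evidence of the switch); 1 marks a one-shot transition.
#'
#' @param correct logical vector of correct responses to the relevant
#'   stimuli, ordered from the first trial of the new block.
#' @return list of class `"TransitionOutcome"`: `trialsToSwitch`, `isFluke`,
#'   `isOneShot`, `converged` (FALSE when no qualifying run exists, in which
#'   case `trialsToSwitch` is the block length as a sentinel).
#' @export
switchingSpeed <- function(correct) {
  correct <- as.logical(correct)
  n <- length(correct)
  runStart <- NA_integer_
  if (n >= 3) {
    ok <- correct[1:(n - 2)] & correct[2:(n - 1)] & correct[3:n]
    if (any(ok)) runStart <- which(ok)[1]
  }
  if (is.na(runStart))
    return(structure(list(trialsToSwitch = n, isFluke = FALSE,
                          isOneShot = FALSE, converged = FALSE),
                     class = "TransitionOutcome"))
  tts <- runStart - 1L
  structure(list(trialsToSwitch = tts, isFluke = tts == 0L,
                 isOneShot = tts == 1L, converged = TRUE),
            class = "TransitionOutcome")
}

# per-transition relevant-correct sequences; direction decides what counts:
# after a switch *to* a visual block, correct licks to the rewarded grating;
# after a switch *to* an odour block, correct ignores of irrelevant gratings
transitionOutcomes <- function(tr) {
  transRows <- which(tr$trial_in_block == 0 & tr$block_index > 0)
  keep <- !(tr$block_cap_hit[transRows - 1])
  out <- lapply(transRows, function(r) {
    bi <- tr$block_index[r]
    blk <- tr[tr$block_index == bi, , drop = FALSE]
    newType <- blk$block_type[1]
    if (newType == "VISUAL") {
      rel <- blk$final_cue == "VISUAL_1"
      correct <- blk$licked_final[rel]
      direction <- "odour_to_visual"
      relPos <- which(rel)
    } else {
      rel <- blk$has_irrelevant
      correct <- !blk$licked_irrelevant[rel]
      direction <- "visual_to_odour"
      relPos <- which(rel)
    }
    sp <- switchingSpeed(correct)
    # elapsed trials counted over all block trials preceding the run start
    tts <- if (sp$converged) relPos[sp$trialsToSwitch + 1L] - 1L else nrow(blk)
    data.frame(transition = NA_integer_, firstTrial = tr$trial[r],
               direction = direction, trialsToSwitch = tts,
               isFluke = sp$converged & tts == 0L,
               isOneShot = sp$converged & tts == 1L,
               converged = sp$converged)
  })
  out <- do.call(rbind, out)
  out$transition <- seq_len(nrow(out))
  out$afterCap <- !keep
  out
}

lastTransitionTrial <- function(blk) {
  tp <- which(blk$transition_phase)
  if (length(tp)) max(tp) else 0L
}

rateOf <- function(licks) if (length(licks)) mean(licks) else NA_real_

#' Summarise the switching behaviour of a session
#'
#' Per-direction switching-speed distributions with flukes excluded from the
#' one-shot proportion and speed statistics, plus behavioural d-prime per
#' stimulus class computed on stable-period trials only (outside transition
#' periods and at least `stableMargin` trials after the transition period
#' ended).
#'
#' @param log a [SessionLog].
#' @param stableMargin trials after transition-period end before a trial
#'   counts as stable (default 5).
#' @return list of class `"BehaviourSummary"`: `transitions` (data.frame,
#'   one row per non-cap transition), `oneShotProportion` (named per
#'   direction, flukes and unconverged-after-cap transitions excluded),
#'   `histogram` (per direction, table of trials-to-switch), `dprime`
#'   (data.frame per stimulus class), `transitionCount`.
#' @export
summarizeTransitions <- function(log, stableMargin = 5L) {
  tr <- trialTable(log)
  if (!any(tr$trial_in_block == 0 & tr$block_index > 0))
    stop("log contains no completed block transition")
  outcomes <- transitionOutcomes(tr)
  valid <- outcomes[!outcomes$afterCap, , drop = FALSE]
  if (nrow(valid) == 0)
    warning("all transitions followed cap-forced block ends")

  oneShot <- vapply(TRANSITION_DIRECTIONS, function(d) {
    g <- valid[valid$direction == d & !valid$isFluke, , drop = FALSE]
    if (nrow(g) == 0) NA_real_ else mean(g$isOneShot)
  }, numeric(1))
  hist <- lapply(TRANSITION_DIRECTIONS, function(d)
    table(valid$trialsToSwitch[valid$direction == d & !valid$isFluke]))
  names(hist) <- TRANSITION_DIRECTIONS

  # stable-period trials: outside transition periods, >= stableMargin trials
  # after the last transition-phase trial of the block
  stable <- rep(FALSE, nrow(tr))
  for (bi in unique(tr$block_index)) {
    sel <- which(tr$block_index == bi)
    blk <- tr[sel, , drop = FALSE]
    cut <- lastTransitionTrial(blk)
    from <- if (cut == 0L) 1L else cut + stableMargin + 1L
    if (from <= nrow(blk)) stable[sel[from:nrow(blk)]] <- TRUE
  }
  st <- tr[stable, , drop = FALSE]
  vis <- st[st$block_type == "VISUAL", , drop = FALSE]
  odo <- st[st$block_type == "ODOUR", , drop = FALSE]
  classes <- list(
    visual_in_visual = list(h = vis$licked_final[vis$final_cue == "VISUAL_1"],
                            f = vis$licked_final[vis$final_cue == "VISUAL_2"]),
    visual_in_odour = list(
      h = odo$licked_irrelevant[odo$has_irrelevant &
                                  odo$irrelevant_cue == "VISUAL_1"],
      f = odo$licked_irrelevant[odo$has_irrelevant &
                                  odo$irrelevant_cue == "VISUAL_2"]),
    odour = list(h = odo$licked_final[odo$final_cue == "ODOUR_1"],
                 f = odo$licked_final[odo$final_cue == "ODOUR_2"]))
  dp <- do.call(rbind, lapply(names(classes), function(nm) {
    cl <- classes[[nm]]
    n <- length(cl$h) + length(cl$f)
    if (n == 0 || !length(cl$h) || !length(cl$f))
      return(data.frame(class = nm, hitRate = NA, faRate = NA,
                        bdPrime = NA, n = n))
    d <- behaviouralDprime(rateOf(cl$h), rateOf(cl$f), n)
    data.frame(class = nm, hitRate = d$hitRate, faRate = d$faRate,
               bdPrime = d$bdPrime, n = n)
  }))

  structure(list(transitions = valid, oneShotProportion = oneShot,
                 histogram = hist, dprime = dp,
                 transitionCount = nrow(valid)),
            class = "BehaviourSummary")
}

#' @export
print.BehaviourSummary <- function(x, ...) {
  cat("BehaviourSummary:", x$transitionCount, "transitions\n")
  for (d in names(x$oneShotProportion))
    cat(sprintf("  %s: one-shot proportion %.3f (flukes excluded)\n",
                d, x$oneShotProportion[[d]]))
  print(x$dprime, row.names = FALSE)
  invisible(x)
}

#' Prediction-error amplitude by transition outcome
#'
#' For each odour-to-visual transition the model's prediction-error
#' amplitude is the sum of the absolute values of the two components of the
#' mismatch signal at the end of the first post-transition trial (by default
#' the noise-corrupted signal chi', which is what drives the belief update).
#' One-shot and slower transitions (flukes excluded) are compared with a
#' two-sided rank-sum test after randomly sampling up to `nSample`
#' transitions per group.
#'
#' @param trace belief-trace data.frame from [runAgent()].
#' @param log the matching [SessionLog].
#' @param nSample transitions sampled per group (default 70).
#' @param signal `"chi_noisy"` (default) or `"chi"`.
#' @param seed optional seed for the subsampling.
#' @return list with `medianOneShot`, `medianSlower`, `statistic`,
#'   `pValue` (NA when a group is empty), `nOneShot`, `nSlower`.
#' @export
peAmplitudeByOutcome <- function(trace, log, nSample = 70L,
                                 signal = c("chi_noisy", "chi"), seed = NULL) {
  signal <- match.arg(signal)
  if (!is.null(seed)) set.seed(seed)
  tr <- trialTable(log)
  outcomes <- transitionOutcomes(tr)
  outcomes <- outcomes[outcomes$direction == "odour_to_visual" &
                         !outcomes$afterCap & !outcomes$isFluke, , drop = FALSE]
  cols <- if (signal == "chi_noisy") c("chi_noisy_1", "chi_noisy_2")
          else c("chi_1", "chi_2")
  amp <- abs(trace[[cols[1]]]) + abs(trace[[cols[2]]])
  ampAt <- amp[match(outcomes$firstTrial, trace$trial)]
  oneShot <- ampAt[outcomes$isOneShot]
  slower <- ampAt[!outcomes$isOneShot]
  pick <- function(x) if (length(x) > nSample) sample(x, nSample) else x
  oneShot <- pick(oneShot[!is.na(oneShot)])
  slower <- pick(slower[!is.na(slower)])
  res <- list(medianOneShot = median(oneShot), medianSlower = median(slower),
              statistic = NA_real_, pValue = NA_real_,
              nOneShot = length(oneShot), nSlower = length(slower))
  if (length(oneShot) && length(slower)) {
    wt <- wilcox.test(oneShot, slower, alternative = "two.sided", exact = FALSE)
    res$statistic <- unname(wt$statistic)
    res$pValue <- wt$p.value
  }
  res
}
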