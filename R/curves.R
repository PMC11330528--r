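TRANSITION_DIRECTIONS <- c("odour_to_visual", "visual_to_odour")

# normalise a trials table (pretty SessionLog data.frame or raw integer-coded
# list from the simulator) into the integer vectors the curve code needs
curveTrialVectors <- function(tr) {
  if (is.list(tr) && !is.data.frame(tr)) tr <- as.data.frame(tr)
  finalCue <- tr$final_cue
  if (is.character(finalCue)) finalCue <- cueCode(finalCue)
  irrCue <- tr$irrelevant_cue
  if (is.character(irrCue)) {
    irrCode <- integer(length(irrCue))
    known <- !is.na(irrCue)
    irrCode[known] <- cueCode(irrCue[known])
    irrCue <- irrCode
  }
  blockType <- tr$block_type
  if (is.character(blockType)) blockType <- match(blockType, BLOCK_TYPES) - 1L
  list(n = nrow(tr),
       finalCue = as.integer(finalCue),
       lickedFinal = as.integer(tr$licked_final),
       irrCue = as.integer(irrCue),
       lickedIrr = as.integer(tr$licked_irrelevant),
       trialInBlock = tr$trial_in_block,
       blockIndex = tr$block_index,
       blockType = as.integer(blockType),
       capHit = as.integer(tr$block_cap_hit))
}

#' Transition-aligned lick-probability curve
#'
#' For every block transition, records for each cue whether the agent licked
#' to it at each trial position within `window` trials of the transition
#' (position 0 = first trial of the new block). Licks to a grating are read
#' from its own presentation step whether it was the reward stimulus (visual
#' block) or the irrelevant stimulus (odour block), matching how lick
#' probabilities are displayed around transitions. Positions at which a cue
#' never occurred (e.g. VISUAL_2 during forced transition trials) stay at
#' zero count and are treated as missing. Transitions following a
#' cap-force-ended block are excluded: they are not behavioural switches.
#'
#' @param x a [SessionLog] (or its trial table).
#' @param window half-width W in trials; positions run -W..W (default 20).
#' @return a \linkS4class{LickProbabilityCurve}.
#' @export
lickProbabilityCurve <- function(x, window = 20L) {
  tr <- if (is(x, "SessionLog")) trialTable(x) else x
  v <- curveTrialVectors(tr)
  if (v$n == 0) stop("empty session log")
  window <- as.integer(window)
  transRows <- which(v$trialInBlock == 0L & v$blockIndex > 0L)
  transRows <- transRows[!(v$capHit[transRows - 1L] == 1L)]
  if (!length(transRows)) stop("log contains no (non-cap) block transition")
  direction <- ifelse(v$blockType[transRows] == 0L,
                      "odour_to_visual", "visual_to_odour")
  P <- 2L * window + 1L
  nT <- length(transRows)
  dn <- list(NULL, TASK_CUES[1:4], as.character(-window:window))
  licks <- array(0, dim = c(nT, 4L, P), dimnames = dn)
  counts <- array(0, dim = c(nT, 4L, P), dimnames = dn)

  rows <- rep(transRows, each = P) + rep(-window:window, times = nT)
  transId <- rep(seq_len(nT), each = P)
  pos <- rep(seq_len(P), times = nT)
  ok <- rows >= 1L & rows <= v$n
  rows <- rows[ok]; transId <- transId[ok]; pos <- pos[ok]

  idxF <- cbind(transId, v$finalCue[rows], pos)
  counts[idxF] <- counts[idxF] + 1
  licks[idxF] <- licks[idxF] + v$lickedFinal[rows]

  hasIrr <- v$irrCue[rows] > 0L
  if (any(hasIrr)) {
    idxI <- cbind(transId[hasIrr], v$irrCue[rows[hasIrr]], pos[hasIrr])
    counts[idxI] <- counts[idxI] + 1
    licks[idxI] <- licks[idxI] + v$lickedIrr[rows[hasIrr]]
  }
  new("LickProbabilityCurve", licks = licks, counts = counts,
      direction = direction, window = window)
}

#' @rdname LickProbabilityCurve-class
#' @export
setMethod("curveWindow", "LickProbabilityCurve", function(x) x@window)

#' @rdname LickProbabilityCurve-class
#' @export
setMethod("curveDirections", "LickProbabilityCurve", function(x) x@direction)

#' @rdname aggregateCurve
#' @export
setMethod("aggregateCurve", "LickProbabilityCurve",
  function(x, transitions = NULL) {
    if (is.null(transitions)) transitions <- seq_along(x@direction)
    P <- 2L * x@window + 1L
    dn <- list(TRANSITION_DIRECTIONS, TASK_CUES[1:4],
               as.character(-x@window:x@window))
    lick <- array(0, dim = c(2L, 4L, P), dimnames = dn)
    count <- array(0, dim = c(2L, 4L, P), dimnames = dn)
    for (d in 1:2) {
      sel <- transitions[x@direction[transitions] == TRANSITION_DIRECTIONS[d]]
      if (length(sel)) {
        lick[d, , ] <- colSums(x@licks[sel, , , drop = FALSE], dims = 1)
        count[d, , ] <- colSums(x@counts[sel, , , drop = FALSE], dims = 1)
      }
    }
    prob <- lick / count
    prob[count == 0] <- NA_real_
    list(prob = prob, count = count)
  })

setMethod("show", "LickProbabilityCurve", function(object) {
  cat("LickProbabilityCurve:", length(object@direction), "transitions (",
      sum(object@direction == "odour_to_visual"), "odour->visual,",
      sum(object@direction == "visual_to_odour"), "visual->odour ), window",
      object@window, "\n")
  invisible(NULL)
})

#' RMSE between two lick-probability curves
#'
#' Root mean squared error over the cells (direction x cue x position)
#' defined in both curves; cells missing in either (zero trials) are
#' excluded.
#'
#' @param a,b \linkS4class{LickProbabilityCurve}s (or aggregates from
#'   [aggregateCurve()]) with identical windows.
#' @return non-negative scalar.
#' @export
curveRmse <- function(a, b) {
  agA <- if (is(a, "LickProbabilityCurve")) aggregateCurve(a) else a
  agB <- if (is(b, "LickProbabilityCurve")) aggregateCurve(b) else b
  if (!identical(dim(agA$prob), dim(agB$prob)))
    stop("curves must share the same window and cue set")
  mask <- agA$count > 0 & agB$count > 0
  if (!any(mask)) stop("no overlapping defined cells; RMSE is undefined")
  sqrt(mean((agA$prob[mask] - agB$prob[mask])^2))
}
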