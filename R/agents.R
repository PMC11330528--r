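#' Basic (tabular SARSA) agent parameters
#'
#' @param epsilon exploration rate of the epsilon-greedy policy, in \[0, 1\].
#' @param alpha learning rate in \[0, 1\]; the basic agent keeps learning with
#'   this rate in both the training and the test phase.
#' @param epsilonPrime optional separate exploration rate applied on steps
#'   whose presented cue is VISUAL_2 (the 3-parameter model variant); `NA`
#'   (default) uses `epsilon` everywhere.
#' @return list of class `"BasicAgentParams"`.
#' @export
basicAgentParams <- function(epsilon = 0.236, alpha = 0.9, epsilonPrime = NA) {
  stopifnot(epsilon >= 0, epsilon <= 1, alpha >= 0, alpha <= 1)
  if (!is.na(epsilonPrime)) stopifnot(epsilonPrime >= 0, epsilonPrime <= 1)
  structure(list(epsilon = epsilon, alpha = alpha,
                 epsilonPrime = epsilonPrime),
            class = "BasicAgentParams")
}

#' Belief-state agent parameters
#'
#' The belief-state agent keeps one Q-table per context (visual block, odour
#' block) and a belief `b = (p(v), p(o))` over the two contexts. Actions are
#' epsilon-greedy on the Q-table of the currently assumed block. At every
#' trial end a block-mismatch signal `chi = d - b` (detected block minus
#' belief) is corrupted multiplicatively, `chi' = chi * (1 + beta * xi)` with
#' a single standard-normal `xi` per trial, optionally scaled by a silencing
#' factor, and drives the belief update `b' = b + zeta * chi'` (clipped to a
#' small positive floor, then renormalised).
#'
#' Defaults are the best-fit values on the primary dataset
#' (`zeta = 0.6858, beta = 1.997, epsilon = 0.049, epsilonPrime = 0.280`,
#' learning rate 0.1 during training and 0 during testing).
#'
#' @param zeta belief switching rate (>= 0).
#' @param beta multiplicative noise factor on the mismatch signal (>= 0).
#' @param epsilon exploration rate.
#' @param epsilonPrime exploration rate substituted on VISUAL_2 cue steps.
#' @param alphaTrain learning rate used during the training phase.
#' @param silencingFactorVisual,silencingFactorOdour multipliers in \[0, 1\]
#'   applied to the mismatch signal on trials whose detected block is visual
#'   or odour respectively; 1 = no silencing.
#' @param epsilonPrimeOdourOnly if TRUE, `epsilonPrime` applies only in odour
#'   blocks; default FALSE (applies to VISUAL_2 in both blocks).
#' @return list of class `"BeliefAgentParams"`.
#' @export
beliefAgentParams <- function(zeta = 0.6858, beta = 1.997, epsilon = 0.049,
                              epsilonPrime = 0.280, alphaTrain = 0.1,
                              silencingFactorVisual = 1,
                              silencingFactorOdour = 1,
                              epsilonPrimeOdourOnly = FALSE) {
  stopifnot(zeta >= 0, beta >= 0, epsilon >= 0, epsilon <= 1,
            alphaTrain >= 0, alphaTrain <= 1,
            silencingFactorVisual >= 0, silencingFactorVisual <= 1,
            silencingFactorOdour >= 0, silencingFactorOdour <= 1)
  if (!is.na(epsilonPrime)) stopifnot(epsilonPrime >= 0, epsilonPrime <= 1)
  structure(list(zeta = zeta, beta = beta, epsilon = epsilon,
                 epsilonPrime = epsilonPrime, alphaTrain = alphaTrain,
                 silencingFactorVisual = silencingFactorVisual,
                 silencingFactorOdour = silencingFactorOdour,
                 epsilonPrimeOdourOnly = isTRUE(epsilonPrimeOdourOnly)),
            class = "BeliefAgentParams")
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action; otherwise the action
#' with the larger Q-value, ties broken uniformly at random.
#'
#' @param qRow named or unnamed numeric of length 2 in the order
#'   (`NO_LICK`, `LICK`).
#' @param epsilon exploration probability in \[0, 1\].
#' @return `"NO_LICK"` or `"LICK"`.
#' @export
selectAction <- function(qRow, epsilon) {
  if (length(qRow) != 2) stop("qRow must have exactly 2 entries")
  if (!is.numeric(epsilon) || epsilon < 0 || epsilon > 1)
    stop("epsilon must lie in [0, 1]")
  if (epsilon > 0 && runif(1) < epsilon)
    return(TASK_ACTIONS[sample.int(2L, 1L)])
  if (qRow[2] > qRow[1]) "LICK"
  else if (qRow[1] > qRow[2]) "NO_LICK"
  else TASK_ACTIONS[sample.int(2L, 1L)]
}

#' One SARSA update
#'
#' Computes the temporal-difference error
#' `delta = r + Q(s', a') - Q(s, a)` and moves `Q(s, a)` by `alpha * delta`.
#' `Q(END_OF_TRIAL, .)` is fixed at 0: it is used as a zero bootstrap target
#' and never updated.
#'
#' @param q Q-table: 4 x 2 matrix with rownames the four non-terminal cues
#'   and colnames `NO_LICK`, `LICK` (see [newQTable()]).
#' @param s,a current cue and action; `sNext,aNext` the next ones
#'   (`sNext = "END_OF_TRIAL"` contributes 0).
#' @param r reward received for (s, a).
#' @param alpha learning rate in \[0, 1\].
#' @return list with the updated `q` and `tdError`
#'   (`delta`, `r`, `qNext`, `qCur`).
#' @export
sarsaUpdate <- function(q, s, a, r, sNext, aNext, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  qCur <- if (s == "END_OF_TRIAL") 0 else q[s, a]
  qNext <- if (sNext == "END_OF_TRIAL") 0 else q[sNext, aNext]
  delta <- r + qNext - qCur
  if (s != "END_OF_TRIAL") q[s, a] <- qCur + alpha * delta
  list(q = q, tdError = list(delta = delta, r = r, qNext = qNext, qCur = qCur))
}

#' Fresh all-zero Q-table
#' @return 4 x 2 zero matrix with cue rownames and action colnames.
#' @export
newQTable <- function() {
  matrix(0, nrow = 4, ncol = 2,
         dimnames = list(TASK_CUES[1:4], TASK_ACTIONS))
}

#' Block-mismatch signal
#'
#' `chi = d - b`, componentwise, where `d` is the detected block as a one-hot
#' pair (visual, odour) and `b` the current belief. The components always sum
#' to zero.
#'
#' @param belief numeric pair `(p(v), p(o))` summing to 1.
#' @param detected one-hot pair, `c(1, 0)` for visual or `c(0, 1)` for odour.
#' @return numeric pair `chi`.
#' @export
computeMismatch <- function(belief, detected) {
  if (!(length(detected) == 2 && all(detected %in% c(0, 1)) &&
        sum(detected) == 1))
    stop("detected must be a one-hot pair")
  detected - belief
}

#' Noise-corrupt (and optionally silence) a mismatch signal
#'
#' A single standard-normal draw `xi` per trial end multiplies both
#' components: `chi' = factor * chi * (1 + beta * xi)`.
#'
#' @param chi mismatch pair from [computeMismatch()].
#' @param beta noise factor >= 0.
#' @param silencingFactor multiplier in \[0, 1\]; 1 = intact signal.
#' @param xi optional fixed standard-normal value (drawn if missing).
#' @return list with `chiNoisy` (pair) and `xi`.
#' @export
corruptMismatch <- function(chi, beta, silencingFactor = 1, xi = NULL) {
  stopifnot(beta >= 0, silencingFactor >= 0, silencingFactor <= 1)
  if (is.null(xi)) xi <- rnorm(1)
  list(chiNoisy = silencingFactor * chi * (1 + beta * xi), xi = xi)
}

#' Belief update
#'
#' `b' = b + zeta * chi'`; each component is clipped to a small positive
#' floor (1e-9) and the clipped pair renormalised to sum to one. If both
#' components hit the floor the belief resets to (0.5, 0.5).
#'
#' @param belief current belief pair.
#' @param chiNoisy noise-corrupted mismatch pair.
#' @param zeta belief switching rate >= 0.
#' @return updated belief pair.
#' @export
updateBelief <- function(belief, chiNoisy, zeta) {
  stopifnot(zeta >= 0)
  b <- belief + zeta * chiNoisy
  floorv <- 1e-9
  b <- pmax(b, floorv)
  if (all(b <= floorv)) b <- c(0.5, 0.5)
  b / sum(b)
}

#' Assumed block given a belief
#'
#' @param belief belief pair `(p(v), p(o))`.
#' @param previous block assumed on the previous trial, used to break exact
#'   ties.
#' @return `"VISUAL"` or `"ODOUR"`.
#' @export
assumedBlock <- function(belief, previous = "VISUAL") {
  if (belief[1] > belief[2]) "VISUAL"
  else if (belief[2] > belief[1]) "ODOUR"
  else previous
}
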