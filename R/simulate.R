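freshAgentState <- function() {
  list(q = numeric(16), belief = c(0.5, 0.5), prevAssumed = 0L)
}

agentKind <- function(params) {
  if (inherits(params, "BeliefAgentParams")) "belief"
  else if (inherits(params, "BasicAgentParams")) "basic"
  else stop("params must come from basicAgentParams() or beliefAgentParams()")
}

agentCodes <- function(params, phase, alphaTest = 0) {
  if (agentKind(params) == "basic") {
    list(kindCode = 0L, epsilon = params$epsilon,
         epsilonPrime = params$epsilonPrime, alpha = params$alpha,
         zeta = 0, beta = 0, silencingFactorVisual = 1,
         silencingFactorOdour = 1, epsilonPrimeOdourOnly = FALSE)
  } else {
    alpha <- if (phase == "train") params$alphaTrain else alphaTest
    list(kindCode = 1L, epsilon = params$epsilon,
         epsilonPrime = params$epsilonPrime, alpha = alpha,
         zeta = params$zeta, beta = params$beta,
         silencingFactorVisual = params$silencingFactorVisual,
         silencingFactorOdour = params$silencingFactorOdour,
         epsilonPrimeOdourOnly = params$epsilonPrimeOdourOnly)
  }
}

#' Run an agent in the task environment
#'
#' Simulates complete trials until at least `nSteps` environment steps have
#' elapsed. In the training phase Q-tables are updated by SARSA (the belief
#' agent updates only the Q-table of the currently assumed block); in the
#' test phase the belief agent's Q-tables are frozen (`alphaTest = 0`) and
#' only its belief is updated, while the basic agent keeps learning with its
#' own `alpha` in both phases. The belief trace records, per trial, the
#' belief `p(v)`, the detected block, the mismatch `chi`, its noise-corrupted
#' version `chi'` and the noise draw `xi`.
#'
#' @param params [basicAgentParams()] or [beliefAgentParams()].
#' @param nSteps number of environment steps to simulate.
#' @param phase `"train"` or `"test"`.
#' @param envCfg an [envConfig()].
#' @param state agent state carried over from a previous run (as returned in
#'   `$state`); fresh zero Q-tables and a (0.5, 0.5) belief if NULL.
#' @param seed optional integer; if given, `set.seed(seed)` is called first.
#' @param recordSteps,recordTrace record per-step detail / the belief trace.
#' @param alphaTest learning rate during the test phase for the belief agent;
#'   values > 0 are honoured with a warning (the standard protocol freezes
#'   learning after training).
#' @return list with `log` (a [SessionLog]), `trace` (data.frame or NULL)
#'   and `state` (final Q-tables, belief, assumed block).
#' @examples
#' res <- runAgent(beliefAgentParams(), nSteps = 2000, phase = "train", seed = 1)
#' res$log
#' @export
runAgent <- function(params, nSteps, phase = c("train", "test"),
                     envCfg = envConfig(), state = NULL, seed = NULL,
                     recordSteps = FALSE, recordTrace = TRUE, alphaTest = 0) {
  phase <- match.arg(phase)
  if (phase == "test" && agentKind(params) == "belief" && alphaTest > 0)
    warning("belief agent learning during the test phase (alphaTest > 0); ",
            "the standard protocol freezes Q-values after training")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- freshAgentState()
  raw <- cpp_simulate(envConfigCodes(envCfg), agentCodes(params, phase, alphaTest),
                      as.integer(nSteps), state, recordSteps,
                      recordTrace && agentKind(params) == "belief")
  log <- SessionLog(prettyTrials(raw$trials),
                    if (recordSteps) prettySteps(raw$steps) else emptyStepTable(),
                    envCfg, seed %||% NA_integer_)
  trace <- if (!is.null(raw$trace)) {
    tdf <- as.data.frame(raw$trace)
    tdf$assumed_block <- blockLabel(tdf$assumed_block)
    tdf$detected_block <- blockLabel(tdf$detected_block)
    tdf$first_of_block <- as.logical(tdf$first_of_block)
    tdf
  }
  list(log = log, trace = trace, state = raw$state)
}

#' Train an agent, then collect frozen-behaviour test data
#'
#' Convenience wrapper for the standard two-phase protocol: SARSA learning
#' for `nTrainSteps`, then `nTestSteps` of simulated behaviour with the
#' belief agent's Q-tables frozen (the basic agent keeps its learning rate).
#'
#' @inheritParams runAgent
#' @param nTrainSteps,nTestSteps steps in each phase (the fitting protocol
#'   uses N/2 and N/2).
#' @return list with `log` and `trace` from the test phase, `trainLog`, and
#'   the final `state`.
#' @export
simulateExperiment <- function(params, nTrainSteps, nTestSteps,
                               envCfg = envConfig(), seed = NULL,
                               recordSteps = FALSE, recordTrace = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  tr <- runAgent(params, nTrainSteps, "train", envCfg,
                 recordSteps = FALSE, recordTrace = FALSE)
  te <- runAgent(params, nTestSteps, "test", envCfg, state = tr$state,
                 recordSteps = recordSteps, recordTrace = recordTrace)
  list(log = te$log, trace = te$trace, trainLog = tr$log, state = te$state)
}

# fast path used by the fitting loops: raw integer-coded trial list, no
# data.frame prettifying
simRawTrials <- function(envCodes, agent, nSteps, state = NULL,
                         recordTrace = FALSE) {
  if (is.null(state)) state <- freshAgentState()
  cpp_simulate(envCodes, agent, as.integer(nSteps), state, FALSE, recordTrace)
}
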