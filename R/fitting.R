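#' Model-fitting configuration
#'
#' Controls the fitting protocol: each candidate parameter set is simulated
#' with SARSA learning for `nSteps/2` steps, then behaviour is collected for
#' a further `nSteps/2` steps (Q-tables frozen for the belief model), the
#' transition-aligned lick-probability curve of the simulated behaviour is
#' compared to the data curve by RMSE, and the RMSE is averaged across the
#' configured seeds (each seed paired with a transition-period variant, by
#' default 2 x V1 + 3 x V2 mirroring the session composition). A global grid
#' search is refined by Nelder-Mead simplex from the best grid points
#' (parameters box-clamped to the grid ranges), and per-fold train/test
#' RMSEs are reported under k-fold cross-validation whose folds are
#' contiguous segments of the data's transition sequence.
#'
#' @param nSteps total simulation steps per candidate evaluation (train and
#'   test each get half). Default 1e5, a desk-scale setting; larger values
#'   tighten the curve estimates.
#' @param grid named list of candidate values per free parameter; NULL picks
#'   the model's default grid (belief: zeta in \[0.05, 1\], beta in \[0, 4\],
#'   epsilon and epsilonPrime in \[0, 0.5\]; basic: epsilon in \[0, 0.5\],
#'   alpha in \[0.05, 1\]).
#' @param nFolds cross-validation folds (>= 2, default 5).
#' @param seeds data.frame with columns `seed` and `variant`; default
#'   `data.frame(seed = 1:5, variant = c("V1","V1","V2","V2","V2"))`.
#' @param localOptStarts number of top grid points used as Nelder-Mead
#'   starting simplices (default 5).
#' @param localMaxit iteration cap per Nelder-Mead run.
#' @param screenSeedRows number of seed rows used in the full-grid pass; the
#'   top `shortlist` candidates are then re-scored with *all* seeds before
#'   local refinement (two-stage budgeted search). Default 0 = use all seeds
#'   everywhere.
#' @param shortlist number of grid candidates re-scored with all seeds when
#'   `screenSeedRows` is active (default 12).
#' @param refineSteps *test-phase* steps per candidate during shortlist
#'   re-scoring and local refinement; NULL (default) uses `nSteps/2`.
#'   Training always runs for `nSteps/2` steps so that candidate agents are
#'   trained exactly like the protocol being fitted; extending only the
#'   frozen test phase cuts the Monte-Carlo noise of the objective where
#'   the search needs precision without changing the agent's state.
#' @param screenSteps test-phase steps per candidate during the full-grid
#'   screen; NULL (default) uses `nSteps/2`.
#' @param cvLocalRefine also run local refinement inside each CV fold
#'   (default FALSE: folds select over the cached grid evaluations).
#' @param envCfg environment configuration used for the simulations.
#' @param alphaTrain training learning rate for the belief model.
#' @return list of class `"FitConfig"`.
#' @export
fitConfig <- function(nSteps = 1e5, grid = NULL, nFolds = 5L,
                      seeds = data.frame(seed = 1:5,
                                         variant = c("V1", "V1", "V2", "V2", "V2")),
                      localOptStarts = 5L, localMaxit = 60L,
                      cvLocalRefine = FALSE, envCfg = envConfig(),
                      alphaTrain = 0.1, screenSeedRows = 0L, shortlist = 12L,
                      refineSteps = NULL, screenSteps = NULL) {
  stopifnot(nFolds >= 2, nSteps >= 2, nrow(seeds) >= 1,
            all(c("seed", "variant") %in% names(seeds)))
  structure(list(nSteps = nSteps, grid = grid, nFolds = as.integer(nFolds),
                 seeds = seeds, localOptStarts = as.integer(localOptStarts),
                 localMaxit = as.integer(localMaxit),
                 cvLocalRefine = isTRUE(cvLocalRefine), envCfg = envCfg,
                 alphaTrain = alphaTrain,
                 screenSeedRows = as.integer(screenSeedRows),
                 shortlist = as.integer(shortlist),
                 refineSteps = refineSteps, screenSteps = screenSteps),
            class = "FitConfig")
}

defaultFitGrid <- function(modelKind) {
  if (modelKind == "belief")
    list(zeta = seq(0.05, 1, length.out = 6),
         beta = seq(0, 4, length.out = 5),
         epsilon = seq(0, 0.5, length.out = 6),
         epsilonPrime = seq(0, 0.5, length.out = 4))
  else
    list(epsilon = seq(0, 0.5, length.out = 11),
         alpha = seq(0.05, 1, length.out = 12))
}

candidateParams <- function(modelKind, values, cfg) {
  v <- as.list(values)
  if (modelKind == "belief")
    beliefAgentParams(zeta = v$zeta, beta = v$beta, epsilon = v$epsilon,
                      epsilonPrime = v$epsilonPrime %||% NA,
                      alphaTrain = cfg$alphaTrain)
  else
    basicAgentParams(epsilon = v$epsilon, alpha = v$alpha,
                     epsilonPrime = v$epsilonPrime %||% NA)
}

# simulate one candidate under one (seed, variant) pair and return the
# aggregated curve of the frozen test phase; NULL if the run is degenerate
# (no behavioural transitions)
simCandidateAgg <- function(params, seed, variant, cfg, window) {
  envC <- cfg$envCfg
  envC$transitionVariant <- variant
  codes <- envConfigCodes(envC)
  half <- as.integer(cfg$nSteps / 2)
  testSteps <- as.integer(cfg$testSteps %||% half)
  set.seed(seed)
  tr <- simRawTrials(codes, agentCodes(params, "train"), half)
  te <- simRawTrials(codes, agentCodes(params, "test"), testSteps,
                     state = tr$state)
  crv <- tryCatch(lickProbabilityCurve(te$trials, window = window),
                  error = function(e) NULL)
  if (is.null(crv)) return(NULL)
  aggregateCurve(crv)
}

seedRmse <- function(aggs, dataAgg) {
  if (any(vapply(aggs, is.null, logical(1)))) return(NA_real_)
  mean(vapply(aggs, function(a)
    tryCatch(curveRmse(a, dataAgg), error = function(e) NA_real_), numeric(1)))
}

clampToBox <- function(p, lower, upper) pmin(pmax(p, lower), upper)

#' Fit a behavioural model to a lick-probability curve
#'
#' Grid search plus Nelder-Mead refinement of the basic (tabular SARSA) or
#' belief-state model against a transition-aligned lick-probability curve,
#' with contiguous-segment cross-validation over the data transitions. Grid
#' candidates are simulated once per seed and cached; CV folds re-aggregate
#' the *data* transitions only (the simulation always uses its own full
#' run, as when fitting experimental sessions).
#'
#' @param data a \linkS4class{LickProbabilityCurve} computed from the data to fit.
#' @param modelKind `"basic"` or `"belief"`.
#' @param cfg a [fitConfig()].
#' @return list of class `"FitResult"`: `bestParams` (named numeric),
#'   `rmse` (full-data RMSE at the optimum), `perFoldRmseTrain`,
#'   `perFoldRmseTest`, `rmseMeanTrain`/`rmseSdTrain`,
#'   `rmseMeanTest`/`rmseSdTest`, `foldParams`, `nCandidates`,
#'   `nDegenerate`, `modelKind`.
#' @export
fitModel <- function(data, modelKind = c("belief", "basic"),
                     cfg = fitConfig()) {
  modelKind <- match.arg(modelKind)
  stopifnot(is(data, "LickProbabilityCurve"))
  grid <- cfg$grid %||% defaultFitGrid(modelKind)
  window <- curveWindow(data)
  cand <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  dataAggFull <- aggregateCurve(data)

  # ---- grid evaluation with cached per-seed aggregates ----
  # optionally two-stage: screen the full grid with the first screenSeedRows
  # seeds, then re-score the shortlist with every seed
  nSeeds <- nrow(cfg$seeds)
  screenRows <- if (cfg$screenSeedRows > 0L) min(cfg$screenSeedRows, nSeeds)
                else nSeeds
  cfgRefine <- cfg
  cfgRefine$testSteps <- cfg$refineSteps
  cfgScreen <- cfg
  cfgScreen$testSteps <- cfg$screenSteps
  simSeeds <- function(params, rows, config = cfg)
    lapply(rows, function(s)
      simCandidateAgg(params, config$seeds$seed[s], config$seeds$variant[s],
                      config, window))
  simCache <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    params <- candidateParams(modelKind, cand[i, , drop = FALSE], cfg)
    simCache[[i]] <- simSeeds(params, seq_len(screenRows), cfgScreen)
  }
  gridRmse <- vapply(simCache, seedRmse, numeric(1), dataAgg = dataAggFull)
  degenerate <- is.na(gridRmse)
  if (all(degenerate)) stop("all grid candidates were degenerate")
  if (screenRows < nSeeds || !is.null(cfg$refineSteps) ||
      !is.null(cfg$screenSteps)) {
    top <- head(order(gridRmse)[!degenerate[order(gridRmse)]], cfg$shortlist)
    for (i in top) {
      params <- candidateParams(modelKind, cand[i, , drop = FALSE], cfg)
      rescored <- simSeeds(params, seq_len(nSeeds), cfgRefine)
      gridRmse[i] <- seedRmse(rescored, dataAggFull)
    }
  }

  paramNames <- names(grid)
  lower <- vapply(grid, min, numeric(1))
  upper <- vapply(grid, max, numeric(1))
  objective <- function(parVec, dataAgg) {
    parVec <- clampToBox(parVec, lower, upper)
    params <- candidateParams(modelKind, setNames(as.list(parVec), paramNames), cfg)
    r <- seedRmse(simSeeds(params, seq_len(nSeeds), cfgRefine), dataAgg)
    if (is.na(r)) 1e6 else r
  }

  refine <- function(startIdx, dataAgg, startRmse) {
    bestPar <- as.numeric(cand[startIdx[1], paramNames])
    bestVal <- startRmse
    for (i in startIdx) {
      st <- as.numeric(cand[i, paramNames])
      opt <- optim(st, objective, dataAgg = dataAgg, method = "Nelder-Mead",
                   control = list(maxit = cfg$localMaxit, reltol = 1e-3))
      if (opt$value < bestVal) {
        bestVal <- opt$value
        bestPar <- clampToBox(opt$par, lower, upper)
      }
    }
    list(par = setNames(bestPar, paramNames), value = bestVal)
  }

  ord <- order(gridRmse)
  bestIdx <- ord[!degenerate[ord]][1]
  starts <- head(ord[!degenerate[ord]], cfg$localOptStarts)
  full <- if (length(starts) && cfg$localMaxit > 0)
    refine(starts, dataAggFull, min(gridRmse[starts]))
  else list(par = setNames(as.numeric(cand[bestIdx, paramNames]), paramNames),
            value = gridRmse[bestIdx])

  # ---- cross-validation over contiguous data-transition segments ----
  M <- length(curveDirections(data))
  foldId <- cut(seq_len(M), breaks = cfg$nFolds, labels = FALSE)
  perTrain <- perTest <- numeric(cfg$nFolds)
  foldParams <- vector("list", cfg$nFolds)
  for (f in seq_len(cfg$nFolds)) {
    trainIdx <- which(foldId != f)
    testIdx <- which(foldId == f)
    aggTrain <- aggregateCurve(data, trainIdx)
    aggTest <- aggregateCurve(data, testIdx)
    rTrain <- vapply(simCache, seedRmse, numeric(1), dataAgg = aggTrain)
    bi <- which.min(rTrain)
    if (cfg$cvLocalRefine) {
      fr <- refine(head(order(rTrain), cfg$localOptStarts), aggTrain, rTrain[bi])
      foldParams[[f]] <- fr$par
      perTrain[f] <- fr$value
      perTest[f] <- objective(fr$par, aggTest)
    } else {
      foldParams[[f]] <- setNames(as.numeric(cand[bi, paramNames]), paramNames)
      perTrain[f] <- rTrain[bi]
      perTest[f] <- seedRmse(simCache[[bi]], aggTest)
    }
  }

  structure(list(modelKind = modelKind, bestParams = full$par,
                 rmse = full$value, perFoldRmseTrain = perTrain,
                 perFoldRmseTest = perTest,
                 rmseMeanTrain = mean(perTrain), rmseSdTrain = sd(perTrain),
                 rmseMeanTest = mean(perTest), rmseSdTest = sd(perTest),
                 foldParams = foldParams, nCandidates = nrow(cand),
                 nDegenerate = sum(degenerate), grid = grid),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat("FitResult (", x$modelKind, " model)\n", sep = "")
  cat("  best parameters:",
      paste(sprintf("%s = %.4g", names(x$bestParams), x$bestParams),
            collapse = ", "), "\n")
  cat(sprintf("  full-data RMSE: %.6f\n", x$rmse))
  cat(sprintf("  CV RMSE train: %.6f +/- %.6f | test: %.6f +/- %.6f (%d folds)\n",
              x$rmseMeanTrain, x$rmseSdTrain, x$rmseMeanTest, x$rmseSdTest,
              length(x$perFoldRmseTest)))
  if (x$nDegenerate > 0)
    cat("  degenerate grid candidates excluded:", x$nDegenerate, "\n")
  invisible(x)
}

#' Fit the two silencing factors
#'
#' With all belief-model parameters held at `baseParams` (fitted on
#' unsilenced data), fits only the two multiplicative factors on the
#' prediction-error signal -- one applied on trials whose detected block is
#' visual, one on odour trials -- to a curve computed from silenced
#' behaviour. Training (unsilenced, factors = 1) is run once per seed and
#' the trained agent state is reused across candidate factor pairs, which
#' only affect the frozen test phase.
#'
#' @param silencedData \linkS4class{LickProbabilityCurve} from the silenced sessions.
#' @param baseParams a [beliefAgentParams()]; returned unchanged.
#' @param cfg a [fitConfig()]; `cfg$grid` may supply `factorVisual` /
#'   `factorOdour` candidate values (default `seq(0, 1, 0.1)` each), and
#'   `cfg$refineSteps`, when set, lengthens the frozen test phase of each
#'   candidate evaluation (training stays at `nSteps/2`).
#' @return list with `factorVisual`, `factorOdour`, `rmse`, and the
#'   untouched `baseParams`.
#' @export
fitSilencingFactors <- function(silencedData, baseParams, cfg = fitConfig()) {
  stopifnot(inherits(baseParams, "BeliefAgentParams"),
            is(silencedData, "LickProbabilityCurve"))
  window <- curveWindow(silencedData)
  dataAgg <- aggregateCurve(silencedData)
  grid <- cfg$grid %||% list(factorVisual = seq(0, 1, by = 0.1),
                             factorOdour = seq(0, 1, by = 0.1))
  half <- as.integer(cfg$nSteps / 2)
  testSteps <- as.integer(cfg$refineSteps %||% half)

  trained <- lapply(seq_len(nrow(cfg$seeds)), function(s) {
    envC <- cfg$envCfg
    envC$transitionVariant <- cfg$seeds$variant[s]
    codes <- envConfigCodes(envC)
    set.seed(cfg$seeds$seed[s])
    list(codes = codes,
         state = simRawTrials(codes, agentCodes(baseParams, "train"), half)$state)
  })

  evalFactors <- function(fv, fo) {
    params <- baseParams
    params$silencingFactorVisual <- fv
    params$silencingFactorOdour <- fo
    aggs <- lapply(seq_len(nrow(cfg$seeds)), function(s) {
      set.seed(cfg$seeds$seed[s] + 10007L)
      te <- simRawTrials(trained[[s]]$codes, agentCodes(params, "test"),
                         testSteps, state = trained[[s]]$state)
      crv <- tryCatch(lickProbabilityCurve(te$trials, window = window),
                      error = function(e) NULL)
      if (is.null(crv)) NULL else aggregateCurve(crv)
    })
    seedRmse(aggs, dataAgg)
  }

  cand <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  vals <- mapply(evalFactors, cand$factorVisual, cand$factorOdour)
  best <- which.min(vals)
  take <- list(par = as.numeric(cand[best, c("factorVisual", "factorOdour")]),
               value = vals[best])
  if (cfg$localMaxit > 0) {
    obj <- function(p) {
      p <- clampToBox(p, c(0, 0), c(1, 1))
      v <- evalFactors(p[1], p[2])
      if (is.na(v)) 1e6 else v
    }
    opt <- optim(take$par, obj, method = "Nelder-Mead",
                 control = list(maxit = cfg$localMaxit, reltol = 1e-3))
    if (opt$value < take$value)
      take <- list(par = clampToBox(opt$par, c(0, 0), c(1, 1)),
                   value = opt$value)
  }
  list(factorVisual = take$par[1], factorOdour = take$par[2],
       rmse = take$value, baseParams = baseParams)
}
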