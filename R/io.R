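#' Write a session log to CSV (one row per step)
#'
#' Columns: `session_id`, `block_index`, `block_type`, `trial_index`,
#' `step_index`, `cue`, `action`, `reward`, `forced`, `transition_phase`,
#' plus `block_cap_hit` on each final step so force-ended blocks survive a
#' round trip. Requires a log recorded with `recordSteps = TRUE`.
#'
#' @param log a [SessionLog] with step-level detail.
#' @param path output file.
#' @param sessionId identifier written into the first column.
#' @export
writeSessionCsv <- function(log, path, sessionId = "session1") {
  st <- stepTable(log)
  if (!nrow(st))
    stop("log has no step-level detail; rerun with recordSteps = TRUE")
  tr <- trialTable(log)
  cap <- tr$block_cap_hit[match(st$trial, tr$trial)] &
    st$step == ave(st$step, st$trial, FUN = max)
  out <- data.frame(session_id = sessionId, block_index = st$block_index,
                    block_type = st$block_type, trial_index = st$trial,
                    step_index = st$step, cue = st$cue, action = st$action,
                    reward = st$reward, forced = st$forced,
                    transition_phase = st$transition_phase,
                    block_cap_hit = cap)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a session log written by [writeSessionCsv()]
#'
#' Rebuilds the per-trial table (cues, lick outcomes, correctness, block
#' structure) from the step rows.
#'
#' @param path CSV file.
#' @param config the [envConfig()] to attach.
#' @return a [SessionLog].
#' @export
readSessionCsv <- function(path, config = envConfig()) {
  st <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("block_index", "block_type", "trial_index", "step_index", "cue",
            "action", "reward", "forced", "transition_phase")
  miss <- setdiff(need, names(st))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"block_cap_hit" %in% names(st)) st$block_cap_hit <- FALSE
  sp <- split(st, st$trial_index)
  rows <- lapply(sp, function(s) {
    s <- s[order(s$step_index), ]
    n <- nrow(s)
    finalCue <- s$cue[n]
    lick <- s$action == "LICK"
    irr <- which(s$cue %in% c("VISUAL_1", "VISUAL_2") &
                   s$block_type == "ODOUR" & s$step_index < s$step_index[n])
    hasIrr <- length(irr) > 0
    relCorrect <- if (finalCue %in% c("VISUAL_1", "ODOUR_1")) lick[n] else !lick[n]
    lickedIrr <- hasIrr && any(lick[irr])
    lickedEot <- any(lick[s$cue == "END_OF_TRIAL"])
    data.frame(trial = s$trial_index[1], block_index = s$block_index[1],
               block_type = s$block_type[1], trial_in_block = NA_integer_,
               transition_phase = any(s$transition_phase),
               has_irrelevant = hasIrr,
               irrelevant_cue = if (hasIrr) s$cue[irr[1]] else NA_character_,
               irrelevant_forced = hasIrr && any(s$forced[irr]),
               licked_irrelevant = lickedIrr, final_cue = finalCue,
               final_forced = s$forced[n], licked_final = lick[n],
               licked_eot = lickedEot, relevant_correct = relCorrect,
               correct = relCorrect && !lickedEot && !lickedIrr,
               reward = sum(s$reward),
               switched_after = FALSE, block_cap_hit = any(s$block_cap_hit))
  })
  tr <- do.call(rbind, rows)
  tr <- tr[order(tr$trial), ]
  tr$trial_in_block <- ave(tr$trial, tr$block_index, FUN = seq_along) - 1L
  tr$switched_after <- c(tr$block_index[-1] != tr$block_index[-nrow(tr)], FALSE)
  rownames(tr) <- NULL
  steps <- data.frame(trial = st$trial_index, block_index = st$block_index,
                      block_type = st$block_type, step = st$step_index,
                      cue = st$cue, action = st$action, reward = st$reward,
                      forced = st$forced,
                      transition_phase = st$transition_phase, delta = NA_real_)
  SessionLog(tr, steps, config)
}

#' Write agent parameters as JSON
#'
#' Keys: `zeta`, `beta`, `epsilon`, `epsilon_prime`, `alpha`,
#' `silencing_factor_visual`, `silencing_factor_odour` (belief model);
#' `epsilon`, `alpha`, `epsilon_prime` (basic model).
#'
#' @param params [beliefAgentParams()] or [basicAgentParams()].
#' @param path output file.
#' @export
writeAgentParamsJson <- function(params, path) {
  x <- if (inherits(params, "BeliefAgentParams"))
    list(model = "belief", zeta = params$zeta, beta = params$beta,
         epsilon = params$epsilon, epsilon_prime = params$epsilonPrime,
         alpha = params$alphaTrain,
         silencing_factor_visual = params$silencingFactorVisual,
         silencing_factor_odour = params$silencingFactorOdour)
  else
    list(model = "basic", epsilon = params$epsilon, alpha = params$alpha,
         epsilon_prime = params$epsilonPrime)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read agent parameters from JSON written by [writeAgentParamsJson()]
#' @param path JSON file.
#' @return agent-parameter object.
#' @export
readAgentParamsJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$model, "belief"))
    beliefAgentParams(zeta = x$zeta, beta = x$beta, epsilon = x$epsilon,
                      epsilonPrime = x$epsilon_prime %||% NA,
                      alphaTrain = x$alpha %||% 0.1,
                      silencingFactorVisual = x$silencing_factor_visual %||% 1,
                      silencingFactorOdour = x$silencing_factor_odour %||% 1)
  else
    basicAgentParams(epsilon = x$epsilon, alpha = x$alpha,
                     epsilonPrime = x$epsilon_prime %||% NA)
}

#' Write a belief trace to CSV
#' @param trace trace data.frame from [runAgent()].
#' @param path output file.
#' @export
writeTraceCsv <- function(trace, path) {
  write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a CalciumRecording to plain-text files
#'
#' Writes `<prefix>_dff.csv` (neurons x frames, with neuron ids),
#' `<prefix>_events.csv`, `<prefix>_trials.csv` and `<prefix>_meta.json`
#' (frame rate, dimensions).
#'
#' @param rec a [CalciumRecording].
#' @param prefix path prefix for the four files.
#' @export
writeCalciumCsv <- function(rec, prefix) {
  m <- dff(rec)
  write.csv(data.frame(neuron = rownames(m), m, check.names = FALSE),
            paste0(prefix, "_dff.csv"), row.names = FALSE)
  write.csv(as.data.frame(taskEvents(rec)), paste0(prefix, "_events.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(trialInfo(rec)), paste0(prefix, "_trials.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(frame_rate = frameRate(rec), n_neurons = nrow(m),
                            n_frames = ncol(m)),
                       paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a CalciumRecording written by [writeCalciumCsv()]
#' @param prefix path prefix used when writing.
#' @return a [CalciumRecording].
#' @export
readCalciumCsv <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  d <- read.csv(paste0(prefix, "_dff.csv"), check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$neuron
  ev <- read.csv(paste0(prefix, "_events.csv"))
  ti <- read.csv(paste0(prefix, "_trials.csv"))
  CalciumRecording(m, frameRate = meta$frame_rate, events = ev, trialInfo = ti)
}

#' Write an environment configuration as JSON
#' @param config an [envConfig()].
#' @param path output file.
#' @export
writeEnvConfigJson <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read an environment configuration written by [writeEnvConfigJson()]
#' @param path JSON file.
#' @return an [envConfig()].
#' @export
readEnvConfigJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  envConfig(pIrrelevantVisual = x$pIrrelevantVisual,
            blockAccuracyThreshold = x$blockAccuracyThreshold,
            blockAccuracyWindow = x$blockAccuracyWindow,
            ignoreWindow = x$ignoreWindow,
            transitionVariant = x$transitionVariant,
            rewardCorrect = x$rewardCorrect, punish = x$punish,
            maxBlockTrials = x$maxBlockTrials, firstBlock = x$firstBlock,
            forcedTrials = x$forcedTrials, seed = x$seed)
}

#' Write a fit result as JSON
#'
#' Mirrors the best-fit parameter table layout: the fitted parameters plus
#' the mean and SD of the train/test RMSEs across folds.
#'
#' @param fit a `FitResult` from [fitModel()].
#' @param path output file.
#' @export
writeFitResultJson <- function(fit, path) {
  jsonlite::write_json(list(
    model = fit$modelKind,
    fitted_parameters = as.list(fit$bestParams),
    rmse_full_data = fit$rmse,
    rmse_train_mean = fit$rmseMeanTrain, rmse_train_sd = fit$rmseSdTrain,
    rmse_test_mean = fit$rmseMeanTest, rmse_test_sd = fit$rmseSdTest,
    per_fold_rmse_train = fit$perFoldRmseTrain,
    per_fold_rmse_test = fit$perFoldRmseTest),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
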