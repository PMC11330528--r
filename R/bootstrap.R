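#' Percentile-bootstrap confidence interval for a proportion
#'
#' Resamples `subsetN` labels with replacement from the population `nBoot`
#' times, computes the proportion of positives in each resample, and takes
#' the percentile interval (0.5th and 99.5th percentiles at the default 99%
#' level). For binary labels the resampled count of positives is exactly
#' Binomial(subsetN, mean(labels)), which is how the resampling is drawn.
#' Optionally reports whether a reference proportion lies outside the
#' interval.
#'
#' @param labels logical/0-1 vector over the population (e.g. is each neuron
#'   a prediction-error neuron).
#' @param subsetN resample size (e.g. the size of the comparison
#'   population); defaults to `length(labels)`.
#' @param nBoot number of resamples (default 10000, minimum 1000).
#' @param level confidence level (default 0.99).
#' @param reference optional reference proportion to locate w.r.t. the CI.
#' @param seed optional seed.
#' @return list of class `"BootstrapCI"`: `proportion`, `lower`, `upper`,
#'   `nBoot`, `level`, `reference`, `referenceOutside` (NA when no reference
#'   given).
#' @export
bootstrapProportionCi <- function(labels, subsetN = length(labels),
                                  nBoot = 10000L, level = 0.99,
                                  reference = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be binary without NAs")
  if (subsetN < 1 || subsetN > length(labels))
    stop("subsetN must lie in [1, length(labels)]")
  if (nBoot < 1000) stop("nBoot must be at least 1000")
  p <- mean(labels)
  props <- rbinom(nBoot, subsetN, p) / subsetN
  qs <- quantile(props, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  out <- list(proportion = p, lower = qs[1], upper = qs[2],
              nBoot = as.integer(nBoot), level = level,
              reference = reference %||% NA_real_,
              referenceOutside = NA)
  if (!is.null(reference))
    out$referenceOutside <- reference < qs[1] || reference > qs[2]
  structure(out, class = "BootstrapCI")
}

#' @export
print.BootstrapCI <- function(x, ...) {
  cat(sprintf("BootstrapCI: proportion %.4f, %d%% CI [%.4f, %.4f] (%d resamples)\n",
              x$proportion, round(100 * x$level), x$lower, x$upper, x$nBoot))
  if (!is.na(x$reference))
    cat(sprintf("  reference %.4f is %s the interval\n", x$reference,
                if (isTRUE(x$referenceOutside)) "outside" else "inside"))
  invisible(x)
}
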