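#' Construct a CalciumRecording
#'
#' @param dff neurons x frames matrix of dF/F values (or raw fluorescence if
#'   you intend to run [computeDff()] yourself; the assay is stored as given).
#' @param frameRate acquisition rate in Hz.
#' @param events data.frame/DataFrame of task events with columns `type`,
#'   `time_s` and optionally `trial`.
#' @param trialInfo per-trial annotation table (may be empty).
#' @param rowData,colData optional per-neuron / per-frame annotation.
#' @return a `CalciumRecording`.
#' @export
CalciumRecording <- function(dff, frameRate, events,
                             trialInfo = S4Vectors::DataFrame(),
                             rowData = NULL, colData = NULL) {
  dff <- as.matrix(dff)
  if (is.null(rownames(dff)))
    rownames(dff) <- sprintf("neuron_%04d", seq_len(nrow(dff)))
  se <- SummarizedExperiment(assays = list(dff = dff))
  if (!is.null(rowData)) rowData(se) <- S4Vectors::DataFrame(rowData)
  if (!is.null(colData)) colData(se) <- S4Vectors::DataFrame(colData)
  new("CalciumRecording", se, frameRate = as.numeric(frameRate),
      events = S4Vectors::DataFrame(events),
      trialInfo = S4Vectors::DataFrame(trialInfo))
}

#' @rdname CalciumRecording-class
#' @export
setMethod("dff", "CalciumRecording", function(x) assay(x, "dff"))

#' @rdname CalciumRecording-class
#' @export
setMethod("frameRate", "CalciumRecording", function(x) x@frameRate)

#' @rdname CalciumRecording-class
#' @export
setMethod("taskEvents", "CalciumRecording", function(x) x@events)

#' @rdname CalciumRecording-class
#' @export
setMethod("trialInfo", "CalciumRecording", function(x) x@trialInfo)

setMethod("show", "CalciumRecording", function(object) {
  cat("CalciumRecording:", nrow(object), "neurons x", ncol(object),
      "frames at", object@frameRate, "Hz\n")
  cat("  duration:", sprintf("%.1f s", ncol(object) / object@frameRate),
      "|", nrow(object@events), "events |", nrow(object@trialInfo), "trials\n")
  types <- table(object@events$type)
  if (length(types))
    cat("  event types:", paste(sprintf("%s(%d)", names(types), types),
                                collapse = ", "), "\n")
  invisible(NULL)
})

# frame index of a time in seconds: frame k (1-based) samples time (k-1)/rate,
# so t maps to round(t * rate) in 0-based terms, clamped to the trace start
timeToFrame <- function(time_s, frameRate)
  pmax(1L, as.integer(round(time_s * frameRate)) + 1L)

# seconds -> number of frames: round to nearest, minimum 1
spanToFrames <- function(span_s, frameRate) max(1L, as.integer(round(span_s * frameRate)))
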