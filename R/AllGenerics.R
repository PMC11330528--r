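#' @rdname SessionLog-class
#' @param x a `SessionLog`
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))

#' @rdname SessionLog-class
#' @export
setGeneric("stepTable", function(x) standardGeneric("stepTable"))

#' @rdname SessionLog-class
#' @export
setGeneric("blockBoundaries", function(x) standardGeneric("blockBoundaries"))

#' @rdname SessionLog-class
#' @export
setGeneric("sessionConfig", function(x) standardGeneric("sessionConfig"))

#' @rdname CalciumRecording-class
#' @param x a `CalciumRecording`
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))

#' @rdname CalciumRecording-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname CalciumRecording-class
#' @export
setGeneric("taskEvents", function(x) standardGeneric("taskEvents"))

#' @rdname CalciumRecording-class
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' @rdname LickProbabilityCurve-class
#' @param x a `LickProbabilityCurve`
#' @export
setGeneric("curveWindow", function(x) standardGeneric("curveWindow"))

#' @rdname LickProbabilityCurve-class
#' @export
setGeneric("curveDirections", function(x) standardGeneric("curveDirections"))

#' Aggregate a lick-probability curve over its transitions
#'
#' @param x a `LickProbabilityCurve`
#' @param transitions integer indices of the transitions to keep (default all)
#' @return list with arrays `prob` and `count` of dimension
#'   `direction(2) x cue(4) x position(2W+1)`; cells with zero count are `NA`
#'   in `prob` and are treated as missing by [curveRmse()].
#' @export
setGeneric("aggregateCurve",
  function(x, transitions = NULL) standardGeneric("aggregateCurve"))
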