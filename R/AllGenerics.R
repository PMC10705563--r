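#' @rdname MethylReadSet-class
#' @param x a MethylReadSet or StateTrackSet
#' @export
setGeneric("moleculeId", function(x) standardGeneric("moleculeId"))

#' @rdname MethylReadSet-class
#' @export
setGeneric("readQuality", function(x) standardGeneric("readQuality"))

#' @rdname MethylReadSet-class
#' @export
setGeneric("m6aPositions", function(x) standardGeneric("m6aPositions"))

#' @rdname MethylReadSet-class
#' @export
setGeneric("avgMethylation", function(x) standardGeneric("avgMethylation"))

#' @rdname StateTrackSet-class
#' @param x a StateTrackSet
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
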