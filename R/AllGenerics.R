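#' @title Accessor generics
#' @description Accessors for the package's S4 containers. Use these instead
#'   of reaching into slots.
#' @param x an object.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x, ...) standardGeneric("cellIds"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x, ...) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("traceValues", function(x, ...) standardGeneric("traceValues"))

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x, ...) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x, ...) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("sessionDuration", function(x, ...) standardGeneric("sessionDuration"))

#' @rdname accessors
#' @export
setGeneric("epochTable", function(x, ...) standardGeneric("epochTable"))

#' @rdname accessors
#' @export
setGeneric("epochCount", function(x, ...) standardGeneric("epochCount"))

#' @rdname accessors
#' @export
setGeneric("bodyPart", function(x, part, ...) standardGeneric("bodyPart"))

#' @rdname accessors
#' @export
setGeneric("targetPosition", function(x, ...) standardGeneric("targetPosition"))

#' @rdname accessors
#' @export
setGeneric("coregPairs", function(x, ...) standardGeneric("coregPairs"))

#' @rdname accessors
#' @export
setGeneric("embeddingScores", function(x, ...) standardGeneric("embeddingScores"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x, ...) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("assayTags", function(x, ...) standardGeneric("assayTags"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x, ...) standardGeneric("explainedVariance"))

#' @rdname accessors
#' @export
setGeneric("tensorOffsets", function(x, ...) standardGeneric("tensorOffsets"))

#' @rdname accessors
#' @export
setGeneric("tensorData", function(x, ...) standardGeneric("tensorData"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("plantedModulation", function(x, ...) standardGeneric("plantedModulation"))

#' @rdname accessors
#' @export
setGeneric("plantedEvents", function(x, ...) standardGeneric("plantedEvents"))
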