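#' @describeIn accessors cell identifiers of a TraceMatrix.
#' @export
setMethod("cellIds", "TraceMatrix", function(x, ...) x@cellIds)

#' @describeIn accessors sampling rate (samples/s) of a TraceMatrix.
#' @export
setMethod("sampleRate", "TraceMatrix", function(x, ...) x@rate)

#' @describeIn accessors sampling rate of a PoseTrack.
#' @export
setMethod("sampleRate", "PoseTrack", function(x, ...) x@rate)

#' @describeIn accessors sampling rate of a PhotometryRecording.
#' @export
setMethod("sampleRate", "PhotometryRecording", function(x, ...) x@rate)

#' @describeIn accessors cells x samples activity matrix.
#' @export
setMethod("traceValues", "TraceMatrix", function(x, ...) x@values)

#' @describeIn accessors sample times (s) of a TraceMatrix grid.
#' @export
setMethod("sampleTimes", "TraceMatrix", function(x, ...)
  (seq_len(ncol(x@values)) - 1L) / x@rate)

#' @describeIn accessors sample times of a PoseTrack.
#' @export
setMethod("sampleTimes", "PoseTrack", function(x, ...) x@time)

#' @describeIn accessors sample times of a PhotometryRecording.
#' @export
setMethod("sampleTimes", "PhotometryRecording", function(x, ...) x@time)

#' @describeIn accessors number of cells.
#' @export
setMethod("nCells", "TraceMatrix", function(x, ...) nrow(x@values))

#' @describeIn accessors duration of a TraceMatrix (s).
#' @export
setMethod("sessionDuration", "TraceMatrix", function(x, ...)
  ncol(x@values) / x@rate)

#' @describeIn accessors duration of a PoseTrack (s).
#' @export
setMethod("sessionDuration", "PoseTrack", function(x, ...)
  x@time[length(x@time)] + 1 / x@rate)

#' @describeIn accessors epoch table (label, start, end) of BehaviorEpochs.
#' @export
setMethod("epochTable", "BehaviorEpochs", function(x, ...) x@epochs)

#' @describeIn accessors number of epochs, optionally of one label.
#' @param label optional behavior label to count.
#' @export
setMethod("epochCount", "BehaviorEpochs", function(x, label = NULL, ...) {
  df <- x@epochs
  if (!is.null(label)) df <- df[df$label %in% label, , drop = FALSE]
  nrow(df)
})

#' @describeIn accessors n x 2 coordinate matrix of one body part.
#' @export
setMethod("bodyPart", "PoseTrack", function(x, part, ...) {
  if (!part %in% names(x@parts))
    stop("body part '", part, "' not present; available: ",
         paste(names(x@parts), collapse = ", "))
  x@parts[[part]]
})

#' @describeIn accessors n x 2 food-target coordinates (or NULL).
#' @export
setMethod("targetPosition", "PoseTrack", function(x, ...) x@target)

#' @describeIn accessors pair table (idA, idB) of a CoRegistrationMap.
#' @export
setMethod("coregPairs", "CoRegistrationMap", function(x, ...) x@pairs)

#' @describeIn accessors samples x dims score matrix of a ClusterEmbedding.
#' @export
setMethod("embeddingScores", "ClusterEmbedding", function(x, ...) x@scores)

#' @describeIn accessors per-sample behavior labels of a ClusterEmbedding.
#' @export
setMethod("sampleLabels", "ClusterEmbedding", function(x, ...) x@labels)

#' @describeIn accessors per-sample assay tags of a ClusterEmbedding.
#' @export
setMethod("assayTags", "ClusterEmbedding", function(x, ...) x@assay)

#' @describeIn accessors explained-variance fractions of retained components.
#' @export
setMethod("explainedVariance", "ClusterEmbedding", function(x, ...)
  x@explainedVar)

#' @describeIn accessors offsets (s) of an EventAlignedTensor.
#' @export
setMethod("tensorOffsets", "EventAlignedTensor", function(x, ...) x@offsets)

#' @describeIn accessors events x offsets x cells array.
#' @export
setMethod("tensorData", "EventAlignedTensor", function(x, ...) x@data)

#' @describeIn accessors cell ids of an EventAlignedTensor.
#' @export
setMethod("cellIds", "EventAlignedTensor", function(x, ...) x@cellIds)

#' @describeIn accessors planted GroundTruth of a SessionBundle.
#' @export
setMethod("groundTruth", "SessionBundle", function(x, ...) x@truth)

#' @describeIn accessors planted cells x labels multiplier matrix.
#' @export
setMethod("plantedModulation", "GroundTruth", function(x, ...) x@modulation)

#' @describeIn accessors planted event-count matrix (cells x trace bins).
#' @export
setMethod("plantedEvents", "GroundTruth", function(x, ...) x@events)

setMethod("show", "TraceMatrix", function(object) {
  cat("TraceMatrix:", nrow(object@values), "cells x", ncol(object@values),
      "samples @", object@rate, "samples/s (",
      sprintf("%.1f", ncol(object@values) / object@rate), "s )\n")
})

setMethod("show", "PoseTrack", function(object) {
  cat("PoseTrack:", length(object@time), "samples @", object@rate,
      "samples/s; parts:", paste(names(object@parts), collapse = ", "),
      if (!is.null(object@target)) "; target present" else "", "\n")
})

setMethod("show", "BehaviorEpochs", function(object) {
  tab <- table(object@epochs$label)
  cat("BehaviorEpochs:", nrow(object@epochs), "epochs (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
})

setMethod("show", "CoRegistrationMap", function(object) {
  cat("CoRegistrationMap:", nrow(object@pairs), "cell pairs\n")
})

setMethod("show", "PhotometryRecording", function(object) {
  cat("PhotometryRecording:", length(object@time), "samples @", object@rate,
      "samples/s\n")
})

setMethod("show", "EventAlignedTensor", function(object) {
  d <- dim(object@data)
  cat("EventAlignedTensor ('", object@label, "'): ", d[1L], " events x ",
      d[2L], " offsets x ", d[3L], " cells; window (",
      object@window[1L], ", ", object@window[2L], ") s; ",
      object@nDropped, " truncated events dropped\n", sep = "")
})

setMethod("show", "SessionBundle", function(object) {
  cat("SessionBundle\n  ")
  show(object@pose)
  cat("  ")
  show(object@epochs)
  cat("  ")
  show(object@traces)
})

setMethod("show", "ClusterEmbedding", function(object) {
  cat("ClusterEmbedding:", nrow(object@scores), "samples x",
      ncol(object@scores), "dims; labels:",
      paste(unique(object@labels), collapse = ", "), "\n")
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf(
    "DecodingResult: mean accuracy %.3f (chance %.2f) over %d folds (%d skipped)\n",
    object@meanAccuracy, object@chance,
    length(object@foldAccuracy), object@nSkipped))
})
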