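#' Construct a PoseTrack
#'
#' @param time numeric sample times (s), strictly increasing, zero-based.
#' @param parts named list of n x 2 coordinate matrices (cm).
#' @param target optional n x 2 food-target coordinates (cm).
#' @param arena arena descriptor, e.g.
#'   `list(shape = "circular", center = c(0, 0), radius = 30)` or
#'   `list(shape = "rectangular", wallHeight = 10)`.
#' @param rate sampling rate (samples/s); inferred from `time` if missing.
#' @return a [PoseTrack-class] object.
#' @export
PoseTrack <- function(time, parts, target = NULL, arena = list(),
                      rate = NULL) {
  if (is.null(rate)) rate <- 1 / median(diff(time))
  parts <- lapply(parts, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  if (!is.null(target)) {
    target <- as.matrix(target)
    storage.mode(target) <- "double"
  }
  new("PoseTrack", time = as.numeric(time), parts = parts, target = target,
      arena = arena, rate = rate)
}

#' Construct BehaviorEpochs
#'
#' @param label character labels (or a data.frame with label/start/end).
#' @param start,end numeric epoch bounds (s), half-open `[start, end)`.
#' @return a [BehaviorEpochs-class] object.
#' @export
BehaviorEpochs <- function(label = character(), start = numeric(),
                           end = numeric()) {
  if (is.data.frame(label)) {
    df <- label[, c("label", "start", "end")]
  } else {
    df <- data.frame(label = as.character(label), start = as.numeric(start),
                     end = as.numeric(end), stringsAsFactors = FALSE)
  }
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  new("BehaviorEpochs", epochs = df)
}

#' Construct a TraceMatrix
#'
#' @param values numeric matrix, cells x samples (df/F).
#' @param cellIds character cell identifiers; default `cell_1 ...`.
#' @param rate sampling rate (samples/s).
#' @return a [TraceMatrix-class] object.
#' @export
TraceMatrix <- function(values, cellIds = NULL, rate) {
  values <- unname(as.matrix(values))
  storage.mode(values) <- "double"
  if (is.null(cellIds)) cellIds <- paste0("cell_", seq_len(nrow(values)))
  new("TraceMatrix", values = values, cellIds = as.character(cellIds),
      rate = rate)
}

#' Construct a CoRegistrationMap
#'
#' @param idA,idB paired cell ids in sessions A and B (or a data.frame with
#'   columns idA/idB in `idA`).
#' @return a [CoRegistrationMap-class] object.
#' @export
CoRegistrationMap <- function(idA, idB = NULL) {
  if (is.data.frame(idA)) {
    df <- data.frame(idA = as.character(idA$idA), idB = as.character(idA$idB),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(idA = as.character(idA), idB = as.character(idB),
                     stringsAsFactors = FALSE)
  }
  new("CoRegistrationMap", pairs = df)
}

#' Construct a PhotometryRecording
#'
#' @param time numeric sample times (s).
#' @param sig470 calcium-dependent 470-nm channel (a.u.).
#' @param ref405 isosbestic 405-nm reference channel (a.u.).
#' @param rate sampling rate (samples/s); inferred from `time` if missing.
#' @return a [PhotometryRecording-class] object.
#' @export
PhotometryRecording <- function(time, sig470, ref405, rate = NULL) {
  if (is.null(rate)) rate <- 1 / median(diff(time))
  if (rate <= 0) stop("sampling rate must be positive")
  new("PhotometryRecording", time = as.numeric(time),
      sig470 = as.numeric(sig470), ref405 = as.numeric(ref405), rate = rate)
}
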