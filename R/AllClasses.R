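#' @import methods
NULL

.BEHAVIOR_LABELS <- c("approach", "eat", "rear")
.LABEL_PRIORITY <- c("eat", "approach", "rear")

#' PoseTrack: time-indexed body-part coordinates
#'
#' Per-frame xy coordinates (cm) of tracked body parts, an optional food-target
#' position, and an arena descriptor. Time is in seconds, zero-based, sampled
#' uniformly (small jitter tolerated). Missing samples are `NA`.
#'
#' @slot time numeric, strictly increasing sample times (s).
#' @slot parts named list of n x 2 matrices (columns x, y in cm), one per part.
#' @slot target n x 2 matrix of food-target coordinates, or `NULL`.
#' @slot arena list describing the enclosure: either
#'   `list(shape = "circular", center = c(x, y), radius = r)` or
#'   `list(shape = "rectangular", wallHeight = h)`.
#' @slot rate numeric, nominal sampling rate (samples/s).
#' @exportClass PoseTrack
setClass("PoseTrack",
  representation(time = "numeric", parts = "list", target = "ANY",
                 arena = "list", rate = "numeric"),
  prototype(target = NULL, arena = list())
)

setValidity("PoseTrack", function(object) {
  n <- length(object@time)
  if (n == 0L) return("empty time vector")
  if (any(diff(object@time) <= 0)) return("time must be strictly increasing")
  if (object@time[1L] < 0) return("time must be zero-based (non-negative)")
  if (length(object@parts) == 0L || is.null(names(object@parts)))
    return("parts must be a named list")
  for (p in names(object@parts)) {
    m <- object@parts[[p]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 2L)
      return(sprintf("part '%s' must be an n x 2 matrix", p))
  }
  if (!is.null(object@target) &&
      (!is.matrix(object@target) || nrow(object@target) != n ||
       ncol(object@target) != 2L))
    return("target must be NULL or an n x 2 matrix")
  if (n > 2L) {
    dt <- diff(object@time)
    if (max(abs(dt - median(dt))) > 0.01 * median(dt) + 1e-9)
      return("sampling must be uniform within 1% jitter")
  }
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    return("rate must be a single positive number")
  TRUE
})

#' BehaviorEpochs: labeled time intervals
#'
#' Labeled behavioral intervals on the half-open convention `[start, end)`,
#' in seconds. Entries of one label must not overlap.
#'
#' @slot epochs data.frame with columns `label`, `start`, `end`.
#' @exportClass BehaviorEpochs
setClass("BehaviorEpochs", representation(epochs = "data.frame"))

setValidity("BehaviorEpochs", function(object) {
  df <- object@epochs
  if (!all(c("label", "start", "end") %in% names(df)))
    return("epochs needs columns label, start, end")
  if (nrow(df) == 0L) return(TRUE)
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    return("non-finite epoch bounds")
  if (any(df$start >= df$end)) return("start must be < end")
  if (any(df$start < 0)) return("epochs must start at or after time 0")
  for (lab in unique(df$label)) {
    sub <- df[df$label == lab, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      return(sprintf("overlapping '%s' epochs", lab))
  }
  TRUE
})

#' TraceMatrix: cells x samples activity
#'
#' Dense cells-by-samples activity matrix in df/F units with cell identifiers
#' and a sampling rate. Sample k (0-based) is at time `k / rate` seconds.
#'
#' @slot values numeric matrix, cells x samples.
#' @slot cellIds character, one id per row.
#' @slot rate numeric, samples/s.
#' @exportClass TraceMatrix
setClass("TraceMatrix",
  representation(values = "matrix", cellIds = "character", rate = "numeric"))

setValidity("TraceMatrix", function(object) {
  if (nrow(object@values) != length(object@cellIds))
    return("cellIds must match rows of values")
  if (anyDuplicated(object@cellIds)) return("duplicated cell ids")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    return("rate must be a single positive number")
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' CoRegistrationMap: cell pairing across two sessions
#'
#' One-to-one pairing of cell ids recorded in two imaging sessions.
#'
#' @slot pairs data.frame with columns `idA`, `idB`.
#' @exportClass CoRegistrationMap
setClass("CoRegistrationMap", representation(pairs = "data.frame"))

setValidity("CoRegistrationMap", function(object) {
  df <- object@pairs
  if (!all(c("idA", "idB") %in% names(df)))
    return("pairs needs columns idA, idB")
  if (anyDuplicated(df$idA) || anyDuplicated(df$idB))
    return("map must be one-to-one (no id repeated on either side)")
  TRUE
})

#' EventAlignedTensor: peri-event activity segments
#'
#' Activity extracted around event onsets: an events x offsets x cells array
#' on a symmetric window, with uniform offsets at the trace sampling rate.
#' Events whose window would be truncated by the session bounds are excluded
#' and counted in `nDropped`.
#'
#' @slot data numeric array, events x offsets x cells.
#' @slot offsets numeric, offset of each sample relative to onset (s).
#' @slot window numeric length 2: seconds before and after onset.
#' @slot label character, behavior label of the events.
#' @slot eventTimes numeric, retained event onsets (s).
#' @slot nDropped integer, events excluded for truncated windows.
#' @slot cellIds character.
#' @exportClass EventAlignedTensor
setClass("EventAlignedTensor",
  representation(data = "array", offsets = "numeric", window = "numeric",
                 label = "character", eventTimes = "numeric",
                 nDropped = "integer", cellIds = "character"))

setValidity("EventAlignedTensor", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-d array")
  if (d[2L] != length(object@offsets)) return("offsets must match dim 2")
  if (d[3L] != length(object@cellIds)) return("cellIds must match dim 3")
  if (d[1L] != length(object@eventTimes)) return("eventTimes must match dim 1")
  if (length(object@window) != 2L || any(object@window <= 0))
    return("window must be two positive numbers (pre, post)")
  TRUE
})

#' PhotometryRecording: dual-channel fiber photometry
#'
#' Interleaved 470-nm calcium-dependent signal and 405-nm isosbestic
#' reference, demultiplexed onto a common time base.
#'
#' @slot time numeric, sample times (s).
#' @slot sig470 numeric, calcium-dependent channel (a.u.).
#' @slot ref405 numeric, isosbestic reference channel (a.u.).
#' @slot rate numeric, samples/s.
#' @exportClass PhotometryRecording
setClass("PhotometryRecording",
  representation(time = "numeric", sig470 = "numeric", ref405 = "numeric",
                 rate = "numeric"))

setValidity("PhotometryRecording", function(object) {
  n <- length(object@time)
  if (length(object@sig470) != n || length(object@ref405) != n)
    return("channel lengths must match time")
  if (any(!is.finite(object@sig470)) || any(!is.finite(object@ref405)))
    return("channels must be finite")
  if (length(object@rate) != 1L || object@rate <= 0)
    return("rate must be a single positive number")
  TRUE
})

#' GroundTruth: planted structure of a synthetic session
#'
#' Everything the generator planted: per-cell rate multipliers per behavior,
#' which behaviors share an identical ensemble across a session pair, the
#' epoch schedule, the planted Poisson event counts (cells x trace samples),
#' and the kernel/noise parameters.
#'
#' @slot modulation numeric matrix, cells x behavior labels; rate multipliers
#'   (dimensionless, >= 0).
#' @slot cellType character, one of `"eatNeg"`, `"eatPos"`, `"approachPos"`,
#'   `"unmod"` per cell.
#' @slot sharedLabels character, behaviors with identical modulation across a
#'   session pair (empty for single sessions).
#' @slot schedule data.frame `label`, `start`, `end` — the planted epochs.
#' @slot events integer matrix, planted event counts per cell per trace bin.
#' @slot seed numeric.
#' @slot kernelTauRise,kernelTauDecay numeric, calcium kernel taus (s).
#' @slot noiseSd numeric, additive Gaussian noise sd (df/F).
#' @slot baseRate numeric, baseline event rate (events/s).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(modulation = "matrix", cellType = "character",
                 sharedLabels = "character", schedule = "data.frame",
                 events = "matrix", seed = "numeric",
                 kernelTauRise = "numeric", kernelTauDecay = "numeric",
                 noiseSd = "numeric", baseRate = "numeric"))

setValidity("GroundTruth", function(object) {
  if (any(object@modulation < 0)) return("rate multipliers must be >= 0")
  if (nrow(object@modulation) != length(object@cellType))
    return("cellType must match modulation rows")
  TRUE
})

#' SessionBundle: one complete synthetic session
#'
#' Pose, epochs and traces sharing one time base, plus the planted truth.
#'
#' @slot pose PoseTrack.
#' @slot epochs BehaviorEpochs.
#' @slot traces TraceMatrix.
#' @slot truth GroundTruth.
#' @exportClass SessionBundle
setClass("SessionBundle",
  representation(pose = "PoseTrack", epochs = "BehaviorEpochs",
                 traces = "TraceMatrix", truth = "GroundTruth"))

#' ClusterEmbedding: behavior-labeled low-dimensional scores
#'
#' Principal-component scores of behavior-labeled population samples, with
#' per-sample behavior labels, per-sample assay tags and explained-variance
#' fractions of the retained components.
#'
#' @slot scores numeric matrix, samples x dims.
#' @slot labels character, per-sample behavior label.
#' @slot assay character, per-sample assay tag.
#' @slot explainedVar numeric, explained-variance fraction per component.
#' @slot loadings numeric matrix, cells x dims.
#' @exportClass ClusterEmbedding
setClass("ClusterEmbedding",
  representation(scores = "matrix", labels = "character", assay = "character",
                 explainedVar = "numeric", loadings = "matrix"))

setValidity("ClusterEmbedding", function(object) {
  if (nrow(object@scores) != length(object@labels))
    return("labels must match score rows")
  if (length(object@assay) &&
      length(object@assay) != nrow(object@scores))
    return("assay tags must match score rows")
  if (ncol(object@scores) < 1L) return("need >= 1 dimension")
  if (any(!is.finite(object@scores))) return("scores must be finite")
  TRUE
})

#' DecodingDataset: matched behavior / non-behavior samples
#'
#' Feature rows (one per selected time point, columns = cells), a binary
#' label, and the time stamp of each row for temporal gap enforcement.
#' Class counts are equal by construction.
#'
#' @slot features numeric matrix, rows x cells.
#' @slot label character, `"behavior"` or `"non"` per row.
#' @slot time numeric, sample time of each row (s).
#' @slot behavior character, the decoded behavior label.
#' @exportClass DecodingDataset
setClass("DecodingDataset",
  representation(features = "matrix", label = "character", time = "numeric",
                 behavior = "character"))

setValidity("DecodingDataset", function(object) {
  n <- nrow(object@features)
  if (length(object@label) != n || length(object@time) != n)
    return("label/time must match feature rows")
  tab <- table(object@label)
  if (length(tab) != 2L || tab[[1L]] != tab[[2L]])
    return("class counts must be equal")
  TRUE
})

#' DecodingResult: cross-validated decoding accuracies
#'
#' @slot foldAccuracy numeric, accuracy of each evaluated fold.
#' @slot meanAccuracy numeric.
#' @slot chance numeric, 0.5 for matched two-class decoding.
#' @slot nFolds integer, folds requested.
#' @slot nSkipped integer, folds skipped for losing a class.
#' @exportClass DecodingResult
setClass("DecodingResult",
  representation(foldAccuracy = "numeric", meanAccuracy = "numeric",
                 chance = "numeric", nFolds = "integer", nSkipped = "integer"))

setValidity("DecodingResult", function(object) {
  if (length(object@foldAccuracy) &&
      (any(object@foldAccuracy < 0) || any(object@foldAccuracy > 1)))
    return("accuracies must lie in [0, 1]")
  TRUE
})
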