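## Plain-text readers and writers for the five input kinds: pose tables,
## epoch tables, trace matrices, co-registration maps and photometry
## recordings, plus a key-value session manifest.

#' Write / read a pose table
#'
#' Comma-separated with a header row: `time_s`, then `<part>_x` / `<part>_y`
#' per body part, optional `<part>_likelihood` columns, and optional
#' `target_x` / `target_y`. On reading, coordinates whose likelihood falls
#' below `likelihoodThreshold` are flagged missing (`NA`).
#'
#' @param pose a [PoseTrack-class].
#' @param file path.
#' @return `writePoseTrack` returns `file` invisibly; `readPoseTrack`
#'   returns a [PoseTrack-class].
#' @export
writePoseTrack <- function(pose, file) {
  df <- data.frame(time_s = pose@time)
  for (p in names(pose@parts)) {
    df[[paste0(p, "_x")]] <- pose@parts[[p]][, 1L]
    df[[paste0(p, "_y")]] <- pose@parts[[p]][, 2L]
  }
  if (!is.null(pose@target)) {
    df$target_x <- pose@target[, 1L]
    df$target_y <- pose@target[, 2L]
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writePoseTrack
#' @param likelihoodThreshold samples with a part likelihood below this are
#'   flagged missing.
#' @param arena arena descriptor attached to the track.
#' @export
readPoseTrack <- function(file, likelihoodThreshold = 0.9, arena = list()) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("pose table needs a time_s column")
  xcols <- grep("_x$", names(df), value = TRUE)
  partNames <- setdiff(sub("_x$", "", xcols), "target")
  parts <- list()
  for (p in partNames) {
    m <- cbind(df[[paste0(p, "_x")]], df[[paste0(p, "_y")]])
    lk <- paste0(p, "_likelihood")
    if (lk %in% names(df)) m[df[[lk]] < likelihoodThreshold, ] <- NA_real_
    parts[[p]] <- m
  }
  target <- if (all(c("target_x", "target_y") %in% names(df)))
    cbind(df$target_x, df$target_y) else NULL
  PoseTrack(df$time_s, parts, target = target, arena = arena)
}

#' Write / read an epoch table
#'
#' Comma-separated `label`, `start_s`, `end_s`.
#'
#' @param epochs a [BehaviorEpochs-class].
#' @param file path.
#' @export
writeBehaviorEpochs <- function(epochs, file) {
  df <- epochTable(epochs)
  utils::write.csv(
    data.frame(label = df$label, start_s = df$start, end_s = df$end),
    file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeBehaviorEpochs
#' @export
readBehaviorEpochs <- function(file) {
  df <- utils::read.csv(file)
  BehaviorEpochs(df$label, df$start_s, df$end_s)
}

#' Write / read a trace matrix
#'
#' Dense comma-separated matrix with a cell-id header row; each subsequent
#' row is one sample (so columns are cells). The sampling rate travels in
#' the session manifest, or is supplied on reading.
#'
#' @param traces a [TraceMatrix-class].
#' @param file path.
#' @export
writeTraceMatrix <- function(traces, file) {
  m <- t(traceValues(traces))
  colnames(m) <- cellIds(traces)
  utils::write.csv(as.data.frame(m), file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTraceMatrix
#' @param rate sampling rate (samples/s) of the stored traces.
#' @export
readTraceMatrix <- function(file, rate) {
  df <- utils::read.csv(file, check.names = FALSE)
  TraceMatrix(t(as.matrix(df)), colnames(df), rate)
}

#' Write / read a co-registration map
#'
#' Two-column comma-separated id table (`idA`, `idB`).
#'
#' @param map a [CoRegistrationMap-class].
#' @param file path.
#' @export
writeCoRegistrationMap <- function(map, file) {
  utils::write.csv(coregPairs(map), file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCoRegistrationMap
#' @export
readCoRegistrationMap <- function(file) {
  CoRegistrationMap(utils::read.csv(file, colClasses = "character"))
}

#' Write / read a photometry recording
#'
#' Three-column comma-separated table: `time_s`, `sig470`, `ref405`.
#'
#' @param rec a [PhotometryRecording-class].
#' @param file path.
#' @export
writePhotometry <- function(rec, file) {
  utils::write.csv(
    data.frame(time_s = rec@time, sig470 = rec@sig470, ref405 = rec@ref405),
    file, row.names = FALSE)
  invisible(file)
}

#' @rdname writePhotometry
#' @export
readPhotometry <- function(file) {
  df <- utils::read.csv(file)
  PhotometryRecording(df$time_s, df$sig470, df$ref405)
}

#' Write / read a key-value manifest
#'
#' Plain text `key: value` lines recording sampling rates, seed and other
#' session metadata.
#'
#' @param values named list or vector.
#' @param file path.
#' @export
writeManifest <- function(values, file) {
  writeLines(paste0(names(values), ": ",
                    vapply(values, format, character(1))), file)
  invisible(file)
}

#' @rdname writeManifest
#' @export
readManifest <- function(file) {
  lines <- readLines(file)
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  out <- lapply(kv, function(x) {
    num <- suppressWarnings(as.numeric(x[2L]))
    if (is.na(num)) x[2L] else num
  })
  names(out) <- vapply(kv, `[`, character(1), 1L)
  out
}

#' Write a complete synthetic session to a directory
#'
#' Emits `pose.csv`, `epochs.csv`, `traces.csv` and `manifest.txt`
#' (sampling rates and seed) under `dir`.
#'
#' @param bundle a [SessionBundle-class].
#' @param dir output directory (created if needed).
#' @export
writeSessionBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writePoseTrack(bundle@pose, file.path(dir, "pose.csv"))
  writeBehaviorEpochs(bundle@epochs, file.path(dir, "epochs.csv"))
  writeTraceMatrix(bundle@traces, file.path(dir, "traces.csv"))
  writeManifest(list(behavior_rate = sampleRate(bundle@pose),
                     trace_rate = sampleRate(bundle@traces),
                     seed = bundle@truth@seed),
                file.path(dir, "manifest.txt"))
  invisible(dir)
}
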