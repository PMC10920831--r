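## Behavioral epoch detection from pose tracks: speed, approach-to-food,
## rearing, and rasterization of labeled intervals onto arbitrary time grids.

#' Head position of a pose track
#'
#' The head is taken as the midpoint of the two ear coordinates (the tracked
#' parts are nose, ears and tailbase; "head" itself is not tracked). The nose
#' is available as an alternative.
#'
#' @param pose a [PoseTrack-class].
#' @param method `"ears"` (midpoint of `earL`/`earR`, the default) or a part
#'   name such as `"nose"`.
#' @return n x 2 matrix of head coordinates (cm).
#' @export
headPosition <- function(pose, method = "ears") {
  method <- match.arg(method[1L], c("ears", names(pose@parts)))
  if (method == "ears") {
    if (!all(c("earL", "earR") %in% names(pose@parts)))
      stop("ear-midpoint head position needs parts 'earL' and 'earR'")
    (bodyPart(pose, "earL") + bodyPart(pose, "earR")) / 2
  } else {
    bodyPart(pose, method)
  }
}

#' Per-sample speed of a body part
#'
#' Central-difference displacement over time, optionally boxcar-smoothed.
#' The first and last samples are filled with the nearest interior value.
#'
#' @param pose a [PoseTrack-class].
#' @param part body-part name, or `"head"` for the ear midpoint.
#' @param smoothingWindow boxcar width in seconds (0 = no smoothing).
#' @return numeric speed (cm/s), one value per pose sample.
#' @export
computeSpeed <- function(pose, part = "head", smoothingWindow = 0) {
  if (smoothingWindow < 0) stop("smoothingWindow must be >= 0")
  xy <- if (part == "head") headPosition(pose) else bodyPart(pose, part)
  tt <- pose@time
  n <- length(tt)
  if (n < 3L) return(rep(0, n))
  dx <- xy[3:n, 1L] - xy[1:(n - 2L), 1L]
  dy <- xy[3:n, 2L] - xy[1:(n - 2L), 2L]
  dt <- tt[3:n] - tt[1:(n - 2L)]
  v <- c(NA_real_, sqrt(dx^2 + dy^2) / dt, NA_real_)
  v[1L] <- v[2L]
  v[n] <- v[n - 1L]
  k <- max(1L, round(smoothingWindow * pose@rate))
  if (k > 1L) {
    if (k %% 2L == 0L) k <- k + 1L
    sm <- stats::filter(v, rep(1 / k, k), sides = 2)
    v2 <- as.numeric(sm)
    # fill boxcar edges with nearest smoothed value
    first <- which(!is.na(v2))[1L]
    if (!is.na(first)) {
      last <- max(which(!is.na(v2)))
      v2[seq_len(first - 1L)] <- v2[first]
      if (last < n) v2[(last + 1L):n] <- v2[last]
      v <- v2
    }
  }
  v
}

.distanceToTarget <- function(pose, method = "ears") {
  if (is.null(pose@target)) stop("pose track has no food-target coordinates")
  hp <- headPosition(pose, method)
  sqrt(rowSums((hp - pose@target)^2))
}

#' Detect approach-to-food epochs
#'
#' An approach epoch is a maximal run of samples during which the animal moves
#' continuously toward the food target: the head-to-target distance is
#' non-increasing sample-to-sample (up to a jitter tolerance), speed stays at
#' or above `minSpeed` throughout, and the net distance decrease over the run
#' is at least `minDecrease`.
#'
#' @param pose a [PoseTrack-class] with target coordinates.
#' @param minDecrease minimum net decrease in distance to target (cm).
#' @param minSpeed minimum speed maintained at all samples (cm/s).
#' @param jitterTol per-sample tolerated distance increase (cm), absorbing
#'   pose-tracking noise that would otherwise fragment epochs.
#' @param speedSmoothing boxcar window (s) for the speed criterion.
#' @return a [BehaviorEpochs-class] of `"approach"` epochs, half-open on the
#'   pose time base.
#' @export
detectApproach <- function(pose, minDecrease = 10, minSpeed = 2,
                           jitterTol = 0.5, speedSmoothing = 0) {
  d <- .distanceToTarget(pose)
  v <- computeSpeed(pose, "head", speedSmoothing)
  n <- length(d)
  tt <- pose@time
  dt <- 1 / pose@rate
  if (n < 2L) return(BehaviorEpochs())
  # transition ok: step toward target up to jitter, both endpoints fast enough
  stepOk <- (diff(d) <= jitterTol) & !is.na(d[-n]) & !is.na(d[-1L])
  fastOk <- !is.na(v) & v >= minSpeed
  transOk <- stepOk & fastOk[-n] & fastOk[-1L]
  runs <- rle(as.logical(transOk))
  starts <- integer(); ends <- integer()
  pos <- 1L
  for (i in seq_along(runs$lengths)) {
    len <- runs$lengths[i]
    if (isTRUE(runs$values[i])) {
      i0 <- pos              # first sample of run
      i1 <- pos + len        # last sample of run (len transitions)
      if (d[i0] - d[i1] >= minDecrease) {
        starts <- c(starts, i0)
        ends <- c(ends, i1)
      }
    }
    pos <- pos + len
  }
  if (!length(starts)) return(BehaviorEpochs())
  BehaviorEpochs("approach", tt[starts], tt[ends] + dt)
}

#' Detect rearing epochs
#'
#' In a circular arena, rearing is flagged when the head is within `margin`
#' cm of the enclosure wall (head-to-center distance exceeds radius − margin);
#' in a rectangular arena, when the head's vertical coordinate exceeds the
#' wall-height threshold. Contiguous supra-threshold runs become epochs.
#'
#' @param pose a [PoseTrack-class] with an arena descriptor.
#' @param margin wall margin (cm) for circular arenas.
#' @return a [BehaviorEpochs-class] of `"rear"` epochs.
#' @export
detectRearing <- function(pose, margin = 2) {
  arena <- pose@arena
  if (is.null(arena$shape))
    stop("pose track has no arena descriptor")
  hp <- headPosition(pose)
  if (arena$shape == "circular") {
    d <- sqrt((hp[, 1L] - arena$center[1L])^2 +
              (hp[, 2L] - arena$center[2L])^2)
    above <- !is.na(d) & d > (arena$radius - margin)
  } else if (arena$shape == "rectangular") {
    above <- !is.na(hp[, 2L]) & hp[, 2L] > arena$wallHeight
  } else stop("unknown arena shape: ", arena$shape)
  runs <- rle(as.logical(above))
  if (!any(runs$values)) return(BehaviorEpochs())
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  dt <- 1 / pose@rate
  BehaviorEpochs("rear", pose@time[starts[keep]], pose@time[ends[keep]] + dt)
}

#' Rasterize epochs onto a time grid
#'
#' Labels every sample of `timeBase` by the epoch containing it (half-open
#' `[start, end)`); unlabeled samples get `"other"`. Where epochs of
#' different labels overlap, the fixed priority eat > approach > rear wins
#' (remaining labels in alphabetical order), so ties are deterministic.
#'
#' @param epochs a [BehaviorEpochs-class].
#' @param timeBase numeric, monotone sample times (s).
#' @param priority label priority, highest first.
#' @return character vector of per-sample labels.
#' @export
rasterizeEpochs <- function(epochs, timeBase,
                            priority = c("eat", "approach", "rear")) {
  if (is.unsorted(timeBase)) stop("time base must be monotone")
  df <- epochTable(epochs)
  out <- rep("other", length(timeBase))
  if (!nrow(df)) return(out)
  extra <- sort(setdiff(unique(df$label), priority))
  order <- rev(c(priority, extra))  # apply lowest priority first, overwrite
  for (lab in order) {
    sub <- df[df$label == lab, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      hit <- timeBase >= sub$start[i] & timeBase < sub$end[i]
      out[hit] <- lab
    }
  }
  out
}

#' Reconstruct epochs from a per-sample label vector
#'
#' Inverse of [rasterizeEpochs()] up to grid resolution: contiguous runs of
#' one label become half-open epochs on the grid.
#'
#' @param labels character per-sample labels.
#' @param timeBase numeric sample times (s), uniform.
#' @param drop labels to ignore (default `"other"`).
#' @return a [BehaviorEpochs-class].
#' @export
epochsFromLabels <- function(labels, timeBase, drop = "other") {
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(!(runs$values %in% drop))
  if (!length(keep)) return(BehaviorEpochs())
  dt <- if (length(timeBase) > 1L) median(diff(timeBase)) else 1
  BehaviorEpochs(runs$values[keep], timeBase[starts[keep]],
                 timeBase[ends[keep]] + dt)
}
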