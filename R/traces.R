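## Trace-level preprocessing and event-locked quantification: variance-based
## inclusion filter, peri-event tensors, pre/post-eating modulation, mean peak
## amplitude, isosbestic photometry correction, and epoch-mean contrasts.

#' Variance-based cell inclusion filter
#'
#' Keeps cells whose activity variance is at least `fraction` of the maximum
#' variance among non-outlier cells. Outliers are flagged in a first pass as
#' cells with variance above Q3 + 1.5 IQR of the per-cell variances; the
#' reference maximum is then taken over the remaining cells, so a single
#' extreme cell cannot silence the population.
#'
#' @param traces a [TraceMatrix-class].
#' @param fraction inclusion threshold as a fraction of the reference maximum
#'   variance (default 0.10).
#' @return list with `traces` (filtered [TraceMatrix-class]), `excluded`
#'   (dropped cell ids) and `reference` (the reference variance).
#' @export
varianceFilter <- function(traces, fraction = 0.10) {
  vals <- traceValues(traces)
  if (nrow(vals) < 1L) stop("need at least one cell")
  v <- apply(vals, 1L, stats::var)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  outlier <- v > q[2L] + 1.5 * (q[2L] - q[1L])
  ref <- if (all(outlier)) max(v) else max(v[!outlier])
  if (ref == 0) {
    warning("all traces constant; variance reference is 0, keeping all cells")
    keep <- rep(TRUE, length(v))
  } else {
    keep <- v >= fraction * ref
  }
  kept <- TraceMatrix(vals[keep, , drop = FALSE],
                      cellIds(traces)[keep], sampleRate(traces))
  list(traces = kept, excluded = cellIds(traces)[!keep], reference = ref)
}

#' Align traces to event onsets
#'
#' Extracts, for every event and cell, the trace segment covering
#' `[t - pre, t + post)` on the trace grid. Events closer than `pre` to the
#' session start or `post` to its end are dropped and counted.
#'
#' @param traces a [TraceMatrix-class].
#' @param eventTimes numeric event onsets (s).
#' @param window numeric length 2 `(pre, post)` in seconds, both > 0.
#' @param label event label carried on the tensor.
#' @return an [EventAlignedTensor-class].
#' @export
alignToEvents <- function(traces, eventTimes, window = c(5, 5),
                          label = "event") {
  if (length(window) != 2L || any(window <= 0))
    stop("window must be two positive numbers (pre, post)")
  rate <- sampleRate(traces)
  vals <- traceValues(traces)
  n <- ncol(vals)
  nOff <- round(sum(window) * rate)
  offsets <- (seq_len(nOff) - 1L) / rate - window[1L]
  starts <- round((eventTimes - window[1L]) * rate)  # 0-based start index
  ok <- starts >= 0L & (starts + nOff) <= n
  kept <- eventTimes[ok]
  arr <- array(NA_real_, dim = c(length(kept), nOff, nrow(vals)))
  ks <- starts[ok]
  for (e in seq_along(kept)) {
    idx <- (ks[e] + 1L):(ks[e] + nOff)
    arr[e, , ] <- t(vals[, idx, drop = FALSE])
  }
  new("EventAlignedTensor", data = arr, offsets = offsets,
      window = as.numeric(window), label = label, eventTimes = kept,
      nDropped = as.integer(sum(!ok)), cellIds = cellIds(traces))
}

#' Pre/post event modulation per cell
#'
#' For each cell, the mean over events of (mean activity in
#' `[0, postWindow)` minus mean activity in `[-preWindow, 0)`), i.e. the
#' post-minus-pre df/F change at event onset. Negative values indicate
#' suppression after onset.
#'
#' @param tensor an [EventAlignedTensor-class].
#' @param preWindow,postWindow seconds on each side of onset; must fit
#'   inside the tensor window.
#' @return named numeric, one delta (df/F) per cell.
#' @export
prePostModulation <- function(tensor, preWindow = NULL, postWindow = NULL) {
  if (is.null(preWindow)) preWindow <- tensor@window[1L]
  if (is.null(postWindow)) postWindow <- tensor@window[2L]
  if (preWindow > tensor@window[1L] + 1e-9 ||
      postWindow > tensor@window[2L] + 1e-9)
    stop("pre/post windows exceed the tensor window")
  if (dim(tensor@data)[1L] == 0L)
    stop("no retained events; modulation undefined")
  off <- tensor@offsets
  preIdx <- off >= -preWindow & off < 0
  postIdx <- off >= 0 & off < postWindow
  post <- apply(tensor@data[, postIdx, , drop = FALSE], c(1L, 3L), mean)
  pre <- apply(tensor@data[, preIdx, , drop = FALSE], c(1L, 3L), mean)
  delta <- colMeans(post - pre)
  names(delta) <- tensor@cellIds
  delta
}

#' Mean peak amplitude of a trace
#'
#' Average value of the strict local maxima of a series (both neighbors
#' smaller; a plateau counts once, at its first sample). Returns 0 with
#' attribute `nPeaks = 0` when the series has no local maximum.
#'
#' @param trace numeric series (length >= 3).
#' @return scalar mean peak amplitude (df/F) with attribute `nPeaks`.
#' @export
meanPeakAmplitude <- function(trace) {
  if (length(trace) < 3L) stop("need at least 3 samples")
  r <- rle(trace)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(v)
  if (m < 3L) {
    out <- 0
    attr(out, "nPeaks") <- 0L
    return(out)
  }
  isPeak <- c(FALSE, v[2:(m - 1L)] > v[1:(m - 2L)] &
                     v[2:(m - 1L)] > v[3:m], FALSE)
  peaks <- v[isPeak]
  out <- if (length(peaks)) mean(peaks) else 0
  attr(out, "nPeaks") <- length(peaks)
  out
}

#' Isosbestic correction of a photometry recording
#'
#' Least-squares affine fit of the 405-nm reference onto the 470-nm signal
#' over the whole session; the corrected trace is
#' `(sig470 - fit) / fit`, removing any artifact expressible as an affine
#' function of the reference (motion, bleaching) while leaving
#' calcium-dependent transients. Output mean is approximately 0.
#'
#' @param rec a [PhotometryRecording-class] with >= 100 samples.
#' @param robust use a rank-deweighted iterated fit instead of ordinary least
#'   squares.
#' @return numeric corrected df/F series.
#' @export
photometryCorrect <- function(rec, robust = FALSE) {
  sig <- rec@sig470
  ref <- rec@ref405
  if (length(sig) < 100L) stop("need at least 100 samples")
  if (stats::sd(ref) < 1e-12) {
    warning("constant reference channel; falling back to baseline-percentile df/F")
    f0 <- stats::quantile(sig, 0.10, names = FALSE)
    if (f0 == 0) f0 <- mean(sig)
    return((sig - f0) / f0)
  }
  fit <- if (robust) {
    w <- rep(1, length(sig))
    for (i in 1:3) {
      co <- stats::lm.wfit(cbind(1, ref), sig, w)$coefficients
      res <- sig - (co[1L] + co[2L] * ref)
      s <- stats::mad(res)
      if (s < 1e-12) break
      w <- 1 / pmax(1, abs(res / (3 * s)))
    }
    co[1L] + co[2L] * ref
  } else {
    stats::lm.fit(cbind(1, ref), sig)$fitted.values
  }
  (sig - fit) / fit
}

#' Difference of epoch means
#'
#' Mean of a series over ON epochs minus its mean over OFF epochs (e.g. the
#' light ON minus light OFF df/F contrast for stimulation epochs).
#'
#' @param series numeric series.
#' @param time numeric sample times (s) of `series`.
#' @param onEpochs,offEpochs [BehaviorEpochs-class] (labels ignored); both
#'   must cover at least one sample.
#' @return scalar df/F difference.
#' @export
epochMeanDifference <- function(series, time, onEpochs, offEpochs) {
  maskOf <- function(ep) {
    df <- epochTable(ep)
    if (!nrow(df)) stop("empty epoch set")
    m <- rep(FALSE, length(time))
    for (i in seq_len(nrow(df)))
      m <- m | (time >= df$start[i] & time < df$end[i])
    m
  }
  mOn <- maskOf(onEpochs)
  mOff <- maskOf(offEpochs)
  if (!any(mOn) || !any(mOff)) stop("epoch set covers no samples")
  mean(series[mOn]) - mean(series[mOff])
}
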