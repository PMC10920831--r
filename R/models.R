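## Supervised analyses: matched-sample cross-validated decoding, per-cell
## Gaussian GLM behavior coefficients, onset-randomization bootstrap
## classification, and cross-assay weight/profile correlations.

#' Build a matched behavior / non-behavior decoding dataset
#'
#' Positive rows are all trace samples within `(onset, onset + window]` after
#' each onset of the behavior; an equal number of negative rows is sampled
#' uniformly without replacement from samples lying outside all epochs of
#' that behavior. Matched counts put chance accuracy at 50%.
#'
#' @param traces a [TraceMatrix-class].
#' @param epochs a [BehaviorEpochs-class].
#' @param behavior the behavior label to decode.
#' @param windowAfterOnset seconds after each onset to take as positives
#'   (default 2).
#' @param seed integer seed for the negative sample.
#' @return a [DecodingDataset-class].
#' @export
buildDecodingDataset <- function(traces, epochs, behavior,
                                 windowAfterOnset = 2, seed = 1) {
  df <- epochTable(epochs)
  df <- df[df$label == behavior, , drop = FALSE]
  if (!nrow(df)) stop("no '", behavior, "' epochs in the session")
  tt <- sampleTimes(traces)
  pos <- logical(length(tt))
  for (i in seq_len(nrow(df)))
    pos <- pos | (tt > df$start[i] & tt <= df$start[i] + windowAfterOnset)
  inEpoch <- logical(length(tt))
  for (i in seq_len(nrow(df)))
    inEpoch <- inEpoch | (tt >= df$start[i] & tt < df$end[i])
  negPool <- which(!inEpoch & !pos)
  posIdx <- which(pos)
  if (length(negPool) < length(posIdx))
    stop("insufficient non-behavior samples: need ", length(posIdx),
         ", have ", length(negPool))
  negIdx <- withr::with_seed(seed,
    sort(sample(negPool, length(posIdx))))
  idx <- c(posIdx, negIdx)
  vals <- traceValues(traces)
  new("DecodingDataset",
      features = t(vals[, idx, drop = FALSE]),
      label = c(rep("behavior", length(posIdx)), rep("non", length(negIdx))),
      time = tt[idx], behavior = behavior)
}

#' Session inclusion rule for decoding
#'
#' A session enters the decoding analysis only if it contains at least
#' `minCount` epochs of the behavior (default 5).
#'
#' @param epochs a [BehaviorEpochs-class].
#' @param behavior behavior label.
#' @param minCount minimum epoch count.
#' @return logical.
#' @export
sessionInclusion <- function(epochs, behavior, minCount = 5) {
  epochCount(epochs, behavior) >= minCount
}

#' Cross-validated matched-sample decoding
#'
#' Rows are sorted by time and partitioned into `k` contiguous-in-time folds;
#' for each fold, training rows within `minGap` seconds of any validation row
#' are dropped, a softmax (multinomial-logistic) classifier with a small
#' ridge penalty is fit on the remaining training rows, and validation
#' accuracy is recorded. Folds whose training or validation set loses an
#' entire class are skipped with a warning.
#'
#' @param dataset a [DecodingDataset-class].
#' @param k number of folds (default 5).
#' @param minGap minimum train/validation separation in seconds (default 10).
#' @param seed integer seed (classifier fits are deterministic; kept for
#'   interface stability).
#' @param zscore z-score features using training statistics.
#' @param decay ridge penalty of the softmax fit.
#' @return a [DecodingResult-class].
#' @export
crossvalDecode <- function(dataset, k = 5, minGap = 10, seed = 1,
                           zscore = TRUE, decay = 1e-4) {
  n <- nrow(dataset@features)
  if (min(table(dataset@label)) < k)
    stop("need at least k rows per class")
  ord <- order(dataset@time)
  feats <- dataset@features[ord, , drop = FALSE]
  labs <- dataset@label[ord]
  tt <- dataset@time[ord]
  foldId <- cut(seq_len(n), breaks = k, labels = FALSE)
  acc <- numeric(0)
  skipped <- 0L
  for (f in seq_len(k)) {
    val <- foldId == f
    tr <- !val
    lo <- min(tt[val]); hi <- max(tt[val])
    tr <- tr & (tt < lo - minGap | tt > hi + minGap)
    if (length(unique(labs[tr])) < 2L || length(unique(labs[val])) < 2L ||
        sum(tr) < 2L) {
      warning("fold ", f, " lost an entire class; skipped")
      skipped <- skipped + 1L
      next
    }
    xtr <- feats[tr, , drop = FALSE]
    xva <- feats[val, , drop = FALSE]
    if (zscore) {
      mu <- colMeans(xtr)
      sds <- apply(xtr, 2L, stats::sd)
      sds[sds < 1e-12] <- 1
      xtr <- scale(xtr, mu, sds)
      xva <- scale(xva, mu, sds)
    }
    dtr <- data.frame(y = factor(labs[tr], levels = c("behavior", "non")),
                      xtr, check.names = TRUE)
    fit <- withr::with_seed(seed, nnet::multinom(
      y ~ ., data = dtr, decay = decay, trace = FALSE,
      maxit = 200, MaxNWts = 100000))
    dva <- data.frame(xva, check.names = TRUE)
    colnames(dva) <- colnames(dtr)[-1L]
    pred <- as.character(stats::predict(fit, newdata = dva))
    acc <- c(acc, mean(pred == labs[val]))
  }
  if (!length(acc)) stop("all folds skipped")
  new("DecodingResult", foldAccuracy = acc, meanAccuracy = mean(acc),
      chance = 0.5, nFolds = as.integer(k), nSkipped = skipped)
}

#' Behavior coefficient of a single cell
#'
#' Gaussian identity-link GLM of one cell's trace on a 0/1 behavior
#' indicator: the fitted slope is the behavior coefficient, and equals the
#' in-behavior minus out-of-behavior mean activity.
#'
#' @param trace numeric, one cell's activity.
#' @param indicator 0/1 per-sample behavior vector (not constant).
#' @return scalar coefficient (df/F).
#' @export
fitBehaviorGlm <- function(trace, indicator) {
  indicator <- as.numeric(indicator)
  if (length(unique(indicator)) < 2L)
    stop("behavior indicator is constant")
  stats::lm.fit(cbind(1, indicator), trace)$coefficients[[2L]]
}

# behavior indicator on the trace grid from an epoch table
.behaviorIndicator <- function(schedule, tt) {
  ind <- logical(length(tt))
  for (i in seq_len(nrow(schedule)))
    ind <- ind | (tt >= schedule$start[i] & tt < schedule$end[i])
  as.numeric(ind)
}

# redraw epoch starts uniformly, preserving durations, non-overlap and
# session bounds (epochs placed in sorted random order within the free time)
.randomizeOnsets <- function(durations, sessionDuration) {
  free <- sessionDuration - sum(durations)
  if (free <= 0)
    stop("epochs cover the whole session; no placement freedom")
  gaps <- sort(stats::runif(length(durations), 0, free))
  gaps + c(0, cumsum(durations[-length(durations)]))
}

#' Shuffle epoch onsets of one behavior
#'
#' Redraws the start times of all epochs of `behavior` uniformly within the
#' session (durations preserved, non-overlap enforced), leaving other labels
#' untouched. Used to break the alignment between labels and traces, e.g.
#' for decoder chance calibration.
#'
#' @param epochs a [BehaviorEpochs-class].
#' @param behavior behavior label to shuffle.
#' @param sessionDuration session length (s).
#' @param seed integer seed.
#' @return a [BehaviorEpochs-class] with shuffled `behavior` onsets.
#' @export
shuffleEpochOnsets <- function(epochs, behavior, sessionDuration, seed = 1) {
  df <- epochTable(epochs)
  sel <- df$label == behavior
  if (!any(sel)) stop("no '", behavior, "' epochs")
  dur <- df$end[sel] - df$start[sel]
  starts <- withr::with_seed(seed, .randomizeOnsets(dur, sessionDuration))
  out <- rbind(df[!sel, , drop = FALSE],
               data.frame(label = behavior, start = starts,
                          end = starts + dur))
  BehaviorEpochs(out)
}

#' Onset-randomization bootstrap null for a behavior coefficient
#'
#' Redraws the behavior epoch start times `nShuffles` times (durations
#' preserved, non-overlap and session bounds enforced), rebuilds the
#' indicator and recomputes the GLM coefficient, giving the null
#' distribution against which the observed coefficient is judged.
#'
#' @param trace numeric, one cell's activity.
#' @param epochs a [BehaviorEpochs-class]; only `behavior` epochs are used.
#' @param behavior behavior label.
#' @param rate trace sampling rate (samples/s).
#' @param nShuffles number of randomizations (default 100).
#' @param seed integer seed.
#' @return numeric vector of `nShuffles` null coefficients.
#' @export
bootstrapOnsetNull <- function(trace, epochs, behavior, rate,
                               nShuffles = 100, seed = 1) {
  df <- epochTable(epochs)
  df <- df[df$label == behavior, , drop = FALSE]
  if (!nrow(df)) stop("no '", behavior, "' epochs")
  dur <- df$end - df$start
  tt <- (seq_along(trace) - 1L) / rate
  sess <- length(trace) / rate
  withr::with_seed(seed, vapply(seq_len(nShuffles), function(i) {
    starts <- .randomizeOnsets(dur, sess)
    ind <- .behaviorIndicator(data.frame(start = starts, end = starts + dur),
                              tt)
    fitBehaviorGlm(trace, ind)
  }, numeric(1)))
}

#' Classify a cell from its coefficient and bootstrap null
#'
#' `"+"` if the observed coefficient exceeds at least `quantile` of the null
#' values, `"-"` if at least `quantile` of the null values exceed it,
#' otherwise `"ns"`. Exact ties count against significance.
#'
#' @param beta observed coefficient.
#' @param null numeric bootstrap coefficients.
#' @param quantile classification threshold (default 0.95).
#' @return list with `class` (`"+"`, `"-"` or `"ns"`) and `nullQuantile`
#'   (fraction of null values below `beta`).
#' @export
classifyCell <- function(beta, null, quantile = 0.95) {
  if (!length(null)) stop("empty null distribution")
  below <- mean(null < beta)
  above <- mean(null > beta)
  cls <- if (below >= quantile) "+" else if (above >= quantile) "-" else "ns"
  list(class = cls, nullQuantile = below)
}

#' Bootstrap GLM classification of all cells in a session
#'
#' Computes each cell's behavior coefficient, builds a shared
#' onset-randomization null (one shuffled schedule per iteration, applied to
#' all cells), and classifies every cell. All least-squares fits per shuffle
#' are solved jointly across cells.
#'
#' @param traces a [TraceMatrix-class].
#' @param epochs a [BehaviorEpochs-class].
#' @param behavior behavior label.
#' @param nShuffles bootstrap iterations (default 100).
#' @param quantile classification threshold (default 0.95).
#' @param seed integer seed.
#' @return data.frame with `cellId`, `behavior`, `beta`, `nullQuantile`,
#'   `class`.
#' @export
classifyCells <- function(traces, epochs, behavior, nShuffles = 100,
                          quantile = 0.95, seed = 1) {
  df <- epochTable(epochs)
  df <- df[df$label == behavior, , drop = FALSE]
  if (!nrow(df)) stop("no '", behavior, "' epochs")
  vals <- traceValues(traces)
  tt <- sampleTimes(traces)
  sess <- sessionDuration(traces)
  dur <- df$end - df$start
  fitAll <- function(ind)
    stats::lm.fit(cbind(1, ind), t(vals))$coefficients[2L, ]
  beta <- fitAll(.behaviorIndicator(df, tt))
  nulls <- withr::with_seed(seed, {
    m <- matrix(NA_real_, nShuffles, nrow(vals))
    for (i in seq_len(nShuffles)) {
      starts <- .randomizeOnsets(dur, sess)
      m[i, ] <- fitAll(data.frame(start = starts, end = starts + dur) |>
                         .behaviorIndicator(tt))
    }
    m
  })
  cls <- vapply(seq_len(nrow(vals)), function(j)
    classifyCell(beta[j], nulls[, j], quantile)$class, character(1))
  nq <- vapply(seq_len(nrow(vals)), function(j)
    mean(nulls[, j] < beta[j]), numeric(1))
  data.frame(cellId = cellIds(traces), behavior = behavior,
             beta = unname(beta), nullQuantile = nq, class = cls,
             stringsAsFactors = FALSE)
}

#' Cross-assay rank correlation of GLM weights
#'
#' Spearman correlation of per-cell behavior coefficients across two
#' co-registered sessions.
#'
#' @param betaA,betaB named numeric coefficients (names = cell ids) in
#'   sessions A and B.
#' @param map a [CoRegistrationMap-class].
#' @return list with `rho`, `p` and `n`; `rho` is `NA` with a flag when
#'   ranks are constant.
#' @export
weightCorrelation <- function(betaA, betaB, map) {
  pr <- coregPairs(map)
  a <- betaA[pr$idA]
  b <- betaB[pr$idB]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("need at least 3 mapped cells")
  if (stats::sd(rank(a)) == 0 || stats::sd(rank(b)) == 0) {
    warning("constant ranks; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(a),
                degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(a),
       degenerate = FALSE)
}

#' Fisher r-to-z comparison of two correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value.
#'
#' @param r1,r2 correlation coefficients.
#' @param n1,n2 sample sizes (> 3).
#' @return list with `z` and `p`.
#' @export
fisherRToZ <- function(r1, r2, n1, n2) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Cross-assay correlation of event-aligned activity profiles
#'
#' Event-averaged per-cell peri-onset profiles from two sessions are
#' concatenated over the given co-registered cells and correlated (Pearson)
#' across assays.
#'
#' @param tensorA,tensorB [EventAlignedTensor-class] objects on equal offset
#'   grids.
#' @param cells cell ids (present in both tensors) to include.
#' @return list with `rho`, `p` and `n` (profile points).
#' @export
profileCorrelation <- function(tensorA, tensorB, cells) {
  if (length(tensorA@offsets) != length(tensorB@offsets) ||
      max(abs(tensorA@offsets - tensorB@offsets)) > 1e-9)
    stop("tensors must share one offset grid")
  ia <- match(cells, tensorA@cellIds)
  ib <- match(cells, tensorB@cellIds)
  if (anyNA(ia) || anyNA(ib)) stop("cells missing from a tensor")
  profA <- apply(tensorA@data[, , ia, drop = FALSE], c(2L, 3L), mean)
  profB <- apply(tensorB@data[, , ib, drop = FALSE], c(2L, 3L), mean)
  a <- as.numeric(profA); b <- as.numeric(profB)
  if (length(a) <= 3L) stop("need more than 3 profile points")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(a))
}
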