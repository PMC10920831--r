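## Population-geometry analyses: PC embedding of behavior-labeled samples,
## silhouette score with a label-permutation chance distribution, and
## cross-assay cluster conservation via Mahalanobis / center distances.

#' PC embedding of behavior-labeled population activity
#'
#' Fits a PCA on all session samples (cells as variables) and returns the
#' scores of samples whose label is in `keepLabels`, in the top
#' `nComponents` components. Cells are z-scored by default so each
#' contributes on a common footing. The sign of each component is fixed by
#' making its largest-magnitude loading positive.
#'
#' @param traces a [TraceMatrix-class].
#' @param labels per-sample behavior labels (length = samples).
#' @param keepLabels labels retained in the embedding.
#' @param nComponents number of components (default 3).
#' @param zscore z-score each cell before the fit.
#' @param assay optional per-sample assay tag carried onto the embedding.
#' @return a [ClusterEmbedding-class].
#' @export
embedPCA <- function(traces, labels, keepLabels = c("approach", "eat", "rear"),
                     nComponents = 3, zscore = TRUE, assay = NULL) {
  vals <- traceValues(traces)
  if (length(labels) != ncol(vals))
    stop("labels must have one entry per trace sample")
  if (nrow(vals) < nComponents)
    stop("fewer cells (", nrow(vals), ") than components (", nComponents, ")")
  keepLabels <- intersect(keepLabels, unique(labels))
  if (!length(keepLabels)) stop("no samples carry a kept label")
  x <- t(vals)  # samples x cells
  if (zscore) {
    sds <- apply(x, 2L, stats::sd)
    sds[sds == 0] <- 1
    x <- scale(x, center = TRUE, scale = sds)
  }
  pc <- stats::prcomp(x, center = !zscore, scale. = FALSE)
  rot <- pc$rotation[, seq_len(nComponents), drop = FALSE]
  flip <- apply(rot, 2L, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2L, flip, `*`)
  scores <- sweep(pc$x[, seq_len(nComponents), drop = FALSE], 2L, flip, `*`)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- labels %in% keepLabels
  new("ClusterEmbedding",
      scores = scores[keep, , drop = FALSE],
      labels = labels[keep],
      assay = if (is.null(assay)) character() else assay[keep],
      explainedVar = ev[seq_len(nComponents)],
      loadings = rot)
}

#' Concatenate two sessions over co-registered cells
#'
#' Restricts both trace matrices to the mapped cells (row order of the map)
#' and joins their samples column-wise: session A samples first, then
#' session B. Per-sample assay tags are returned alongside.
#'
#' @param tracesA,tracesB [TraceMatrix-class] objects with equal rates.
#' @param map a [CoRegistrationMap-class]; all ids must be present.
#' @param tags assay tag for each session (length 2).
#' @return list with `traces` (joint [TraceMatrix-class], cell ids from
#'   session A) and `assay` (per-sample tag vector).
#' @export
concatenateCoregistered <- function(tracesA, tracesB, map,
                                    tags = c("A", "B")) {
  pr <- coregPairs(map)
  if (!nrow(pr)) stop("empty co-registration map")
  missA <- setdiff(pr$idA, cellIds(tracesA))
  missB <- setdiff(pr$idB, cellIds(tracesB))
  if (length(missA)) stop("ids missing in session A: ",
                          paste(missA, collapse = ", "))
  if (length(missB)) stop("ids missing in session B: ",
                          paste(missB, collapse = ", "))
  ia <- match(pr$idA, cellIds(tracesA))
  ib <- match(pr$idB, cellIds(tracesB))
  joint <- cbind(traceValues(tracesA)[ia, , drop = FALSE],
                 traceValues(tracesB)[ib, , drop = FALSE])
  list(traces = TraceMatrix(joint, pr$idA, sampleRate(tracesA)),
       assay = c(rep(tags[1L], ncol(traceValues(tracesA))),
                 rep(tags[2L], ncol(traceValues(tracesB)))))
}

# mean distance of every point to every cluster, computed in row blocks
# directly from coordinates (no n x n matrix held in memory)
.silhouetteWidthsXY <- function(x, labels) {
  labs <- unique(labels)
  n <- nrow(x)
  sq <- rowSums(x^2)
  onehot <- outer(labels, labs, `==`) * 1  # n x k
  sizes <- colSums(onehot)
  meanTo <- matrix(0, n, length(labs))
  block <- 2000L
  for (b0 in seq(1L, n, by = block)) {
    b1 <- min(b0 + block - 1L, n)
    g <- x[b0:b1, , drop = FALSE] %*% t(x)
    d2 <- pmax(outer(sq[b0:b1], sq, `+`) - 2 * g, 0)
    meanTo[b0:b1, ] <- (sqrt(d2) %*% onehot) / rep(sizes, each = b1 - b0 + 1L)
  }
  s <- numeric(n)
  for (j in seq_along(labs)) {
    rows <- labels == labs[j]
    nk <- sizes[j]
    if (nk == 1L) { s[rows] <- 0; next }
    a <- meanTo[rows, j] * nk / (nk - 1L)
    b <- apply(meanTo[rows, -j, drop = FALSE], 1L, min)
    s[rows] <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  }
  s
}

# silhouette widths from a precomputed distance matrix
.silhouetteWidths <- function(dmat, labels) {
  labs <- unique(labels)
  n <- length(labels)
  meanTo <- sapply(labs, function(l) {
    cols <- labels == l
    rowSums(dmat[, cols, drop = FALSE]) / sum(cols)
  })  # n x nLab, includes self distance (0) in own cluster column
  sizes <- as.integer(table(labels)[labs])
  s <- numeric(n)
  for (j in seq_along(labs)) {
    rows <- labels == labs[j]
    nk <- sizes[j]
    if (nk == 1L) { s[rows] <- 0; next }
    a <- meanTo[rows, j] * nk / (nk - 1L)  # exclude self
    b <- apply(meanTo[rows, -j, drop = FALSE], 1L, min)
    s[rows] <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  }
  s
}

#' Mean silhouette score of a labeled embedding
#'
#' Per-sample silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with
#' Euclidean distances, where `a` is the mean intra-cluster distance and `b`
#' the smallest mean distance to another cluster; samples in singleton
#' clusters get `s = 0` (with a warning). Values near 0 indicate chance-level
#' separation.
#'
#' @param embedding a [ClusterEmbedding-class], or a numeric matrix if
#'   `labels` is supplied.
#' @param labels per-sample labels (only when `embedding` is a matrix).
#' @return mean silhouette score, with attribute `widths` (per-sample).
#' @export
silhouetteScore <- function(embedding, labels = NULL) {
  if (is(embedding, "ClusterEmbedding")) {
    x <- embeddingScores(embedding)
    labels <- sampleLabels(embedding)
  } else {
    x <- as.matrix(embedding)
  }
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 labels")
  if (any(tab < 2L)) warning("singleton cluster(s): silhouette set to 0")
  s <- if (nrow(x) <= 3000L) {
    .silhouetteWidths(as.matrix(stats::dist(x)), labels)
  } else {
    .silhouetteWidthsXY(x, labels)
  }
  out <- mean(s)
  attr(out, "widths") <- s
  out
}

#' Permutation chance distribution of the silhouette score
#'
#' Permutes the label vector `nShuffles` times, recomputing the mean
#' silhouette each time (distances computed once), and reports the observed
#' score's position in the null.
#'
#' @param embedding a [ClusterEmbedding-class].
#' @param nShuffles number of label permutations (default 1000).
#' @param seed integer seed.
#' @return list with `observed`, `null` (numeric of length `nShuffles`) and
#'   `percentile` (fraction of null values below the observed score).
#' @export
chanceSilhouette <- function(embedding, nShuffles = 1000, seed = 1) {
  x <- embeddingScores(embedding)
  labels <- sampleLabels(embedding)
  if (nrow(x) <= 3000L) {
    dmat <- as.matrix(stats::dist(x))
    widths <- function(l) .silhouetteWidths(dmat, l)
  } else {
    widths <- function(l) .silhouetteWidthsXY(x, l)
  }
  observed <- mean(widths(labels))
  null <- withr::with_seed(seed,
    vapply(seq_len(nShuffles), function(i)
      mean(widths(sample(labels))), numeric(1)))
  list(observed = observed, null = null,
       percentile = mean(null < observed))
}

#' Mahalanobis distance of query points to a reference cluster
#'
#' For each query point y, `d_M(y) = sqrt((y - mu)' Sigma^-1 (y - mu))` with
#' mu and Sigma the reference cluster's mean and sample covariance. A
#' singular covariance is ridge-regularized with
#' `lambda = 1e-6 * mean(diag(Sigma))` (with a warning).
#'
#' @param reference numeric matrix, reference cluster points (rows).
#' @param query numeric matrix, query points (rows).
#' @return numeric, one distance per query point.
#' @export
mahalanobisCrossAssay <- function(reference, query) {
  reference <- as.matrix(reference)
  query <- as.matrix(query)
  p <- ncol(reference)
  if (nrow(reference) <= p)
    stop("reference cluster needs more samples than dimensions")
  mu <- colMeans(reference)
  sigma <- stats::cov(reference)
  ok <- tryCatch({solve(sigma); TRUE}, error = function(e) FALSE)
  if (!ok || rcond(sigma) < 1e-12) {
    warning("singular reference covariance; applying ridge regularization")
    sigma <- sigma + diag(1e-6 * mean(diag(sigma)), p)
  }
  sqrt(stats::mahalanobis(query, mu, sigma))
}

#' Cross-assay cluster distances for one behavior
#'
#' Pools Mahalanobis distances in both directions: samples of `behavior` in
#' assay B measured against the assay-A cluster, and vice versa. Computed in
#' the full neural space by default (columns = co-registered cells), or in a
#' PC space if `embed` components are requested.
#'
#' @param joint joint [TraceMatrix-class] from [concatenateCoregistered()].
#' @param labels per-sample behavior labels of the joint matrix.
#' @param assay per-sample assay tags of the joint matrix.
#' @param behavior the behavior to compare across assays.
#' @param embed `NULL` for full neural space, or a number of PCs.
#' @return numeric vector of pooled cross-assay distances.
#' @export
crossAssayDistances <- function(joint, labels, assay, behavior,
                                embed = NULL) {
  x <- t(traceValues(joint))  # samples x cells
  if (!is.null(embed)) {
    emb <- embedPCA(joint, labels, keepLabels = unique(labels),
                    nComponents = embed, assay = assay)
    x <- embeddingScores(emb)
    labels <- sampleLabels(emb)
    assay <- assayTags(emb)
  }
  tags <- unique(assay)
  if (length(tags) != 2L) stop("need exactly two assay tags")
  sel <- labels == behavior
  a <- x[sel & assay == tags[1L], , drop = FALSE]
  b <- x[sel & assay == tags[2L], , drop = FALSE]
  c(mahalanobisCrossAssay(a, b), mahalanobisCrossAssay(b, a))
}

#' Euclidean distance of samples to their pooled cluster center
#'
#' @param samples numeric matrix, points of one behavior pooled across both
#'   assays (rows).
#' @return numeric, per-sample distance to the pooled mean.
#' @export
centerDistance <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stop("need at least 2 samples")
  ctr <- colMeans(samples)
  sqrt(rowSums(sweep(samples, 2L, ctr)^2))
}

#' Rank-sum conservation comparison of cluster distances
#'
#' Two-sample Wilcoxon rank-sum comparison of eat-cluster vs approach-cluster
#' distances, reporting the rank-sum statistic, a normal z approximation
#' (tie-corrected), the two-sided p-value, and which behavior has the
#' smaller (more conserved) distances.
#'
#' @param distancesEat,distancesApproach numeric distance vectors.
#' @return list with `statistic` (rank sum of the eat group), `z`, `p` and
#'   `moreConserved` (`"eat"` or `"approach"`).
#' @export
conservationTest <- function(distancesEat, distancesApproach) {
  x <- distancesEat
  y <- distancesApproach
  if (!length(x) || !length(y)) stop("both distance sets must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sig2 > 0) (w - mu) / sqrt(sig2) else 0
  p <- if (n1 <= 25 && n2 <= 25 && !any(duplicated(c(x, y)))) {
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    2 * stats::pnorm(-abs(z))
  }
  list(statistic = w, z = z, p = min(1, p),
       moreConserved = if (stats::median(x) <= stats::median(y)) "eat"
                       else "approach")
}
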