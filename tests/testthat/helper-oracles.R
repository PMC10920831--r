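# Independent brute-force oracles. These deliberately re-derive each
# quantity with straightforward loops, separate from the package's
# vectorized implementations.

bruteSilhouette <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      other <- which(labels == l)
      b <- min(b, mean(vapply(other, function(j) d(i, j), numeric(1))))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

bruteMahalanobis <- function(reference, query) {
  mu <- colMeans(reference)
  S <- stats::cov(reference)
  apply(as.matrix(query), 1L, function(y) {
    v <- y - mu
    sqrt(drop(t(v) %*% solve(S, v)))
  })
}

# exhaustive interval scan for approach epochs: for every start sample,
# extend while per-step and per-sample rules hold, keep maximal stretches
# with enough net decrease
bruteApproach <- function(d, v, time, dt, minDecrease, minSpeed, jitterTol) {
  n <- length(d)
  okStep <- function(i) d[i + 1L] - d[i] <= jitterTol
  okSamp <- function(i) v[i] >= minSpeed
  out <- NULL
  i <- 1L
  while (i < n) {
    if (okSamp(i) && okSamp(i + 1L) && okStep(i)) {
      j <- i + 1L
      while (j < n && okSamp(j + 1L) && okStep(j)) j <- j + 1L
      if (d[i] - d[j] >= minDecrease)
        out <- rbind(out, c(time[i], time[j] + dt))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

bruteRasterize <- function(epochDf, timeBase,
                           priority = c("eat", "approach", "rear")) {
  allLabs <- c(priority, sort(setdiff(unique(epochDf$label), priority)))
  out <- character(length(timeBase))
  for (k in seq_along(timeBase)) {
    t <- timeBase[k]
    hit <- epochDf$label[epochDf$start <= t & t < epochDf$end]
    out[k] <- if (!length(hit)) "other"
              else allLabs[min(match(hit, allLabs))]
  }
  out
}

# exact two-sided signed-rank p by enumerating all sign assignments
bruteSignedRankP <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dist <- signs %*% r
  pLow <- mean(dist <= w)
  pHigh <- mean(dist >= w)
  min(1, 2 * min(pLow, pHigh))
}

# exact two-sided rank-sum p by enumerating group assignments
bruteRankSumP <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(r), n1)
  dist <- apply(combos, 2L, function(idx) sum(r[idx]))
  pLow <- mean(dist <= w)
  pHigh <- mean(dist >= w)
  min(1, 2 * min(pLow, pHigh))
}

bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  sorted <- p[o]
  for (i in seq_len(n)) q[i] <- min(sorted[i:n] * n / (i:n), 1)
  q <- cummin(rev(q)) |> rev()  # enforce monotone step-up
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# two-pass variance filter, loop-coded
bruteVarianceKeep <- function(values, fraction) {
  v <- numeric(nrow(values))
  for (i in seq_len(nrow(values))) v[i] <- stats::var(values[i, ])
  qs <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  nonOut <- v <= qs[2] + 1.5 * (qs[2] - qs[1])
  ref <- max(v[nonOut])
  which(v >= fraction * ref)
}

# simple pose track helper: head path given directly, ears around it
makePose <- function(headXY, rate = 30, target = NULL, arena = list()) {
  n <- nrow(headXY)
  tt <- (seq_len(n) - 1L) / rate
  off <- cbind(rep(0, n), rep(0.8, n))
  PoseTrack(tt,
            parts = list(nose = headXY + cbind(1, 0)[rep(1, n), ],
                         earL = headXY + off, earR = headXY - off,
                         tailbase = headXY - cbind(3, 0)[rep(1, n), ]),
            target = target, arena = arena, rate = rate)
}

randomEmbedding <- function(n = 30, k = 3, sep = 0, d = 3, seed = 1) {
  set.seed(seed)
  labs <- sample(letters[1:k], n, replace = TRUE)
  while (length(unique(labs)) < k || min(table(labs)) < 2)
    labs <- sample(letters[1:k], n, replace = TRUE)
  centers <- matrix(rnorm(k * d), k) * sep
  x <- centers[match(labs, letters[1:k]), ] + matrix(rnorm(n * d), n)
  list(x = x, labels = labs)
}

smallConfig <- function(...) {
  generatorConfig(nCells = 12, duration = 300, ...)
}
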