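test_that("PCA embedding recovers structure and matches an eigen oracle", {
  set.seed(12)
  n <- 200
  vals <- rbind(matrix(rnorm(3 * n), 3) * c(5, 2, 1), matrix(0, 2, n))
  labels <- sample(c("approach", "eat", "rear"), n, replace = TRUE)
  tm <- TraceMatrix(vals + rnorm(length(vals), 0, 1e-8), rate = 7.5)
  emb <- embedPCA(tm, labels, zscore = FALSE)
  expect_equal(nrow(embeddingScores(emb)), n)
  expect_gt(sum(explainedVariance(emb)), 0.99)
  # scores equal an independent eigendecomposition, given the sign rule
  x <- scale(t(traceValues(tm)), center = TRUE, scale = FALSE)
  eg <- eigen(crossprod(x) / (n - 1))
  for (j in 1:3) {
    vec <- eg$vectors[, j]
    vec <- vec * sign(vec[which.max(abs(vec))])
    expect_equal(unname(embeddingScores(emb)[, j]), unname(drop(x %*% vec)),
                 tolerance = 1e-6)
  }
  expect_error(embedPCA(TraceMatrix(matrix(rnorm(20), 2), rate = 1),
                        rep("eat", 10)), "fewer cells")
})

test_that("concatenation over co-registered cells looks up the right rows", {
  a <- TraceMatrix(matrix(1:12, 3), c("x", "y", "z"), rate = 5)
  map <- CoRegistrationMap(c("x", "y", "z"), c("x", "y", "z"))
  joint <- concatenateCoregistered(a, a, map)
  expect_identical(traceValues(joint$traces),
                   unname(cbind(traceValues(a), traceValues(a))))
  expect_equal(joint$assay, rep(c("A", "B"), each = 4))
  expect_error(concatenateCoregistered(a, a,
                                       CoRegistrationMap(character(),
                                                         character())),
               "empty")
  # permuted map matches a row-lookup oracle
  set.seed(7)
  b <- TraceMatrix(matrix(rnorm(15), 3), c("p", "q", "r"), rate = 5)
  mp <- CoRegistrationMap(c("z", "x"), c("q", "r"))
  jj <- concatenateCoregistered(a, b, mp)
  expect_equal(traceValues(jj$traces)[1, 5:9],
               unname(traceValues(b)["q" == cellIds(b), ]))
  expect_error(concatenateCoregistered(a, b,
                                       CoRegistrationMap("nope", "q")),
               "nope")
})

test_that("silhouette behaves at its limits and matches brute force", {
  # two far-separated tight clusters
  x <- rbind(matrix(rnorm(40, 0, 0.01), 20),
             matrix(rnorm(40, 100, 0.01), 20))
  s <- silhouetteScore(x, rep(c("a", "b"), each = 20))
  expect_gt(as.numeric(s), 0.99)
  # random labels on one blob: near zero
  set.seed(3)
  blob <- matrix(rnorm(2000), 1000, 2)
  s0 <- silhouetteScore(blob, sample(c("a", "b", "c"), 1000, replace = TRUE))
  expect_lt(abs(as.numeric(s0)), 0.05)
  # brute-force agreement on small instances
  for (seed in 1:20) {
    inst <- randomEmbedding(n = sample(8:20, 1), sep = runif(1, 0, 3),
                            seed = seed)
    expect_equal(as.numeric(silhouetteScore(inst$x, inst$labels)),
                 bruteSilhouette(inst$x, inst$labels), tolerance = 1e-12)
  }
  expect_error(silhouetteScore(blob, rep("a", 1000)), "2 labels")
})

test_that("silhouette agrees with the reference library implementation", {
  skip_if_not_installed("cluster")
  for (seed in 1:5) {
    inst <- randomEmbedding(n = 50, sep = runif(1, 0, 3), seed = 400 + seed)
    ref <- cluster::silhouette(as.integer(factor(inst$labels)),
                               dist(inst$x))
    expect_equal(as.numeric(silhouetteScore(inst$x, inst$labels)),
                 mean(ref[, "sil_width"]), tolerance = 1e-12)
  }
})

test_that("blocked and distance-matrix silhouette paths agree", {
  inst <- randomEmbedding(n = 400, sep = 1, seed = 5)
  a <- FeedScope:::.silhouetteWidths(as.matrix(dist(inst$x)), inst$labels)
  b <- FeedScope:::.silhouetteWidthsXY(inst$x, inst$labels)
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("permutation chance of the silhouette is calibrated", {
  inst <- randomEmbedding(n = 60, sep = 4, seed = 2)
  emb <- new("ClusterEmbedding", scores = inst$x, labels = inst$labels,
             assay = character(), explainedVar = rep(1 / 3, 3),
             loadings = diag(3))
  ch <- chanceSilhouette(emb, nShuffles = 200, seed = 9)
  # perfectly separated clusters sit above the entire null
  expect_equal(ch$percentile, 1)
  expect_gt(ch$observed, max(ch$null))
  # fixed seed reproduces the null exactly
  ch2 <- chanceSilhouette(emb, nShuffles = 200, seed = 9)
  expect_identical(ch$null, ch2$null)
})

test_that("chance-silhouette percentile is uniform under random labels", {
  # calibration: on already-random labels the observed percentile should be
  # uniform; checked with a KS test across synthetic repeats
  pct <- vapply(1:60, function(s) {
    inst <- randomEmbedding(n = 40, sep = 0, seed = 1000 + s)
    emb <- new("ClusterEmbedding", scores = inst$x, labels = inst$labels,
               assay = character(), explainedVar = rep(1 / 3, 3),
               loadings = diag(3))
    chanceSilhouette(emb, nShuffles = 60, seed = s)$percentile
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pct, "punif")$p.value), 0.01)
})

test_that("Mahalanobis distances match closed forms and a solve oracle", {
  set.seed(4)
  ref <- matrix(rnorm(300), 60, 5)
  expect_equal(mahalanobisCrossAssay(ref, t(colMeans(ref))), 0,
               tolerance = 1e-9)
  # identity covariance: equals Euclidean distance to the mean
  refI <- matrix(rnorm(40000), 20000, 2)
  q <- matrix(c(3, 4), 1)
  dM <- mahalanobisCrossAssay(refI, q)
  expect_equal(dM, sqrt(sum((c(3, 4) - colMeans(refI))^2)), tolerance = 0.05)
  # random 5-d clusters against the explicit solve-based oracle
  for (rep in 1:10) {
    r <- matrix(rnorm(60 * 5), 60) %*% matrix(runif(25, -1, 1), 5)
    qq <- matrix(rnorm(50), 10, 5)
    expect_equal(mahalanobisCrossAssay(r, qq), bruteMahalanobis(r, qq),
                 tolerance = 1e-9)
  }
  expect_error(mahalanobisCrossAssay(matrix(rnorm(10), 2, 5), q),
               "more samples")
})

test_that("Mahalanobis is invariant under joint affine transforms", {
  set.seed(10)
  ref <- matrix(rnorm(240), 80, 3)
  qq <- matrix(rnorm(30), 10, 3)
  base <- mahalanobisCrossAssay(ref, qq)
  A <- matrix(rnorm(9), 3) + diag(3)
  shift <- rnorm(3)
  tr <- function(m) sweep(m %*% A, 2, shift, `+`)
  expect_equal(mahalanobisCrossAssay(tr(ref), tr(qq)), base,
               tolerance = 1e-6)
})

test_that("center distances are plain Euclidean norms to the pooled mean", {
  same <- matrix(2, 5, 3)
  expect_equal(centerDistance(same), rep(0, 5))
  two <- rbind(c(1, 0), c(-1, 0))
  expect_equal(centerDistance(two), c(1, 1))
  set.seed(11)
  cloud <- matrix(rnorm(60), 20, 3)
  ctr <- colMeans(cloud)
  oracle <- apply(cloud, 1, function(r) sqrt(sum((r - ctr)^2)))
  expect_equal(centerDistance(cloud), oracle, tolerance = 1e-12)
})

test_that("conservation rank-sum test has the right limits and exact p", {
  same <- conservationTest(1:10, 1:10)
  expect_gt(same$p, 0.9)
  apart <- conservationTest(rnorm(100), rnorm(100) + 50)
  expect_lt(apart$p, 1e-6)
  expect_equal(apart$moreConserved, "eat")
  # small-sample p equals the exhaustive rank-enumeration oracle
  set.seed(13)
  for (rep in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    got <- conservationTest(x, y)
    expect_equal(got$p, bruteRankSumP(x, y), tolerance = 1e-9)
    expect_equal(got$statistic, sum(rank(c(x, y))[1:5]))
  }
})

test_that("shared eat ensembles are detected as more conserved", {
  hits <- vapply(1:8, function(s) {
    pair <- generateAssayPair(generatorConfig(nCells = 30, duration = 900),
                              overlap = "eat", dropout = 0, seed = 100 + s)
    joint <- concatenateCoregistered(pair$sessionA@traces,
                                     pair$sessionB@traces, pair$map)
    lab <- c(rasterizeEpochs(pair$sessionA@epochs,
                             sampleTimes(pair$sessionA@traces)),
             rasterizeEpochs(pair$sessionB@epochs,
                             sampleTimes(pair$sessionB@traces)))
    dE <- crossAssayDistances(joint$traces, lab, joint$assay, "eat")
    dA <- crossAssayDistances(joint$traces, lab, joint$assay, "approach")
    stats::median(dE) < stats::median(dA)
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})
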