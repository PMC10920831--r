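scaleRowsToVar <- function(v, n = 400) {
  t(vapply(v, function(vi) {
    x <- rnorm(n)
    x / sd(x) * sqrt(vi)
  }, numeric(n)))
}

test_that("variance filter applies the 10% rule with outlier protection", {
  set.seed(1)
  tm <- TraceMatrix(scaleRowsToVar(c(100, 50, 9)), c("a", "b", "c"),
                    rate = 7.5)
  out <- varianceFilter(tm, 0.10)
  expect_setequal(cellIds(out$traces), c("a", "b"))
  expect_equal(out$excluded, "c")
  # single cell is always kept
  one <- varianceFilter(TraceMatrix(scaleRowsToVar(4), "x", 7.5))
  expect_equal(cellIds(one$traces), "x")
  # all-constant matrix: reference 0, all kept, warning
  flat <- TraceMatrix(matrix(1, 3, 50), rate = 7.5)
  expect_warning(res <- varianceFilter(flat), "constant")
  expect_equal(nCells(res$traces), 3)
})

test_that("variance filter matches a two-pass oracle and is scale-equivariant", {
  set.seed(14)
  for (rep in 1:5) {
    v <- c(runif(199, 0.5, 20), 5000)  # one planted extreme outlier
    vals <- scaleRowsToVar(sample(v))
    tm <- TraceMatrix(vals, rate = 7.5)
    keep <- which(cellIds(tm) %in% cellIds(varianceFilter(tm)$traces))
    expect_equal(keep, bruteVarianceKeep(vals, 0.10))
    scaled <- TraceMatrix(vals * 3.7, rate = 7.5)
    expect_identical(cellIds(varianceFilter(scaled)$traces),
                     cellIds(varianceFilter(tm)$traces))
  }
})

test_that("event alignment slices the trace grid correctly", {
  tm <- TraceMatrix(matrix(2, 1, 100), rate = 10)
  tens <- alignToEvents(tm, c(3, 5), c(1, 1))
  expect_true(all(tensorData(tens) == 2))
  expect_equal(dim(tensorData(tens)), c(2, 20, 1))
  # a delta at the event time peaks at offset 0
  x <- numeric(100); x[51] <- 7  # sample 51 = t 5.0
  tensD <- alignToEvents(TraceMatrix(matrix(x, 1), rate = 10), 5, c(2, 2))
  prof <- tensorData(tensD)[1, , 1]
  expect_equal(tensorOffsets(tensD)[which.max(prof)], 0)
  # events too close to the edges are dropped and counted
  tensE <- alignToEvents(tm, c(0.5, 5, 9.9), c(1, 1))
  expect_equal(tensE@nDropped, 2L)
  expect_equal(tensE@eventTimes, 5)
})

test_that("event alignment matches an index-slicing oracle and is linear", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 400; rate <- 7.5
    x <- matrix(rnorm(3 * n), 3, n)
    ev <- runif(4, 10, 40)
    tens <- alignToEvents(TraceMatrix(x, rate = rate), ev, c(2, 2))
    nOff <- round(4 * rate)
    for (e in seq_along(tens@eventTimes)) {
      i0 <- round((tens@eventTimes[e] - 2) * rate)
      for (cc in 1:3)
        expect_equal(tensorData(tens)[e, , cc], x[cc, (i0 + 1):(i0 + nOff)])
    }
    y <- matrix(rnorm(3 * n), 3, n)
    tx <- tensorData(alignToEvents(TraceMatrix(x, rate = rate), ev, c(2, 2)))
    ty <- tensorData(alignToEvents(TraceMatrix(y, rate = rate), ev, c(2, 2)))
    tz <- tensorData(alignToEvents(TraceMatrix(2 * x - 5 * y, rate = rate),
                                   ev, c(2, 2)))
    expect_equal(tz, 2 * tx - 5 * ty, tolerance = 1e-12)
  }
})

test_that("pre/post modulation recovers step changes and symmetry", {
  rate <- 1
  x <- rep(1, 100)
  events <- c(20, 60)
  for (e in events) x[(e + 1):(e + 5)] <- 0  # drops to 0 at onset for 5 s
  tens <- alignToEvents(TraceMatrix(matrix(x, 1), rate = rate), events,
                        c(5, 5))
  expect_equal(unname(prePostModulation(tens, 5, 5)), -1)
  # trace mirror-symmetric around the event: zero delta
  set.seed(4)
  v <- rnorm(20)
  sym <- numeric(400)
  sym[181:220] <- c(v, rev(v))  # event at t = 20 s, rate 10
  tensS <- alignToEvents(TraceMatrix(matrix(sym, 1), rate = 10), 20, c(2, 2))
  expect_equal(unname(prePostModulation(tensS, 2, 2)), 0, tolerance = 1e-12)
  empty <- alignToEvents(TraceMatrix(matrix(sym, 1), rate = 10),
                         numeric(0), c(2, 2))
  expect_error(prePostModulation(empty), "events")
})

test_that("planted eat- cells show negative pre/post eating modulation", {
  cfg <- generatorConfig(nCells = 40, duration = 1200,
                         fractions = c(eatNeg = 1, eatPos = 0,
                                       approachPos = 0, unmod = 0))
  ses <- generateSession(cfg, seed = 17)
  sched <- epochTable(ses@epochs)
  onsets <- sched$start[sched$label == "eat"]
  tens <- alignToEvents(ses@traces, onsets, c(5, 5), "eat")
  delta <- prePostModulation(tens)
  expect_gte(mean(delta < 0), 0.95)
})

test_that("mean peak amplitude averages strict local maxima", {
  mono <- meanPeakAmplitude(1:10)
  expect_equal(as.numeric(mono), 0)
  expect_equal(attr(mono, "nPeaks"), 0L)
  expect_equal(as.numeric(meanPeakAmplitude(c(0, 1, 0, 3, 0))), 2)
  # plateau counts once
  expect_equal(as.numeric(meanPeakAmplitude(c(0, 2, 2, 0, 4, 0))), 3)
  # noisy sinusoid equals a three-point comparison oracle
  set.seed(6)
  x <- sin(seq(0, 12 * pi, length.out = 500)) + rnorm(500, 0, 0.2)
  peaks <- c()
  for (i in 2:499)
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) peaks <- c(peaks, x[i])
  expect_equal(as.numeric(meanPeakAmplitude(x)), mean(peaks))
})

test_that("isosbestic correction removes affine artifacts exactly", {
  set.seed(2)
  ref <- 1 + cumsum(rnorm(500, 0, 0.01))
  rec <- PhotometryRecording(seq_along(ref) / 20, 2 * ref, ref)
  expect_lt(max(abs(photometryCorrect(rec))), 1e-9)
  recAff <- PhotometryRecording(seq_along(ref) / 20, 3 + 0.5 * ref, ref)
  expect_lt(max(abs(photometryCorrect(recAff))), 1e-9)
  # constant reference falls back to percentile df/F with a warning
  recC <- PhotometryRecording(seq_along(ref) / 20, ref + 1, rep(1, 500))
  expect_warning(out <- photometryCorrect(recC), "constant")
  expect_length(out, 500)
  expect_error(photometryCorrect(
    PhotometryRecording(1:50 / 20, rnorm(50), rnorm(50))), "100")
})

test_that("correction removes the planted artifact but keeps transients", {
  cfg <- generatorConfig()
  ph <- generatePhotometry(cfg, artifactAmplitude = 0.1, seed = 3)
  corrected <- photometryCorrect(ph$recording)
  expect_lt(abs(stats::cor(corrected, ph$artifact)), 0.1)
  expect_lt(abs(mean(corrected)), 0.01)
  tm <- TraceMatrix(matrix(corrected, 1), "fiber",
                    sampleRate(ph$recording))
  prof <- apply(tensorData(alignToEvents(tm, ph$eventTimes, c(2, 2))),
                2, mean)
  offs <- seq(-2, 2 - 1e-9, by = 1 / sampleRate(ph$recording))
  baselineSd <- sd(prof[offs < -0.5])
  expect_gt(max(prof), 3 * baselineSd)
})

test_that("epoch mean difference equals a masked-mean oracle", {
  tt <- seq(0, 99.5, by = 0.5)
  on <- BehaviorEpochs("on", c(10, 50), c(20, 60))
  off <- BehaviorEpochs("off", c(30, 70), c(40, 80))
  x <- as.numeric(tt >= 10 & tt < 20 | tt >= 50 & tt < 60)
  expect_equal(epochMeanDifference(x, tt, on, off), 1)
  expect_equal(epochMeanDifference(rep(3, length(tt)), tt, on, off), 0)
  set.seed(9)
  y <- rnorm(length(tt))
  mOn <- (tt >= 10 & tt < 20) | (tt >= 50 & tt < 60)
  mOff <- (tt >= 30 & tt < 40) | (tt >= 70 & tt < 80)
  expect_equal(epochMeanDifference(y, tt, on, off),
               mean(y[mOn]) - mean(y[mOff]), tolerance = 1e-12)
  expect_error(epochMeanDifference(y, tt, BehaviorEpochs(), off), "empty")
})
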