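test_that("decoding datasets have matched counts and reproducible negatives", {
  # 3 onsets, 2-s window at 7.5 samples/s: 45 positives and 45 negatives
  tm <- TraceMatrix(matrix(rnorm(2 * 4500), 2), rate = 7.5)
  ep <- BehaviorEpochs(rep("eat", 3), c(100, 200, 300), c(110, 210, 310))
  ds <- buildDecodingDataset(tm, ep, "eat", windowAfterOnset = 2, seed = 5)
  expect_equal(sum(ds@label == "behavior"), 45)
  expect_equal(sum(ds@label == "non"), 45)
  ds2 <- buildDecodingDataset(tm, ep, "eat", windowAfterOnset = 2, seed = 5)
  expect_identical(ds@time, ds2@time)
  ds3 <- buildDecodingDataset(tm, ep, "eat", windowAfterOnset = 2, seed = 6)
  expect_false(identical(ds@time, ds3@time))
  expect_error(buildDecodingDataset(tm, ep, "rear"), "rear")
  # positives fall strictly inside (onset, onset + 2]
  posT <- ds@time[ds@label == "behavior"]
  expect_true(all(vapply(posT, function(t)
    any(t > c(100, 200, 300) & t <= c(102, 202, 302)), logical(1))))
  # negatives avoid the behavior epochs entirely
  negT <- ds@time[ds@label == "non"]
  expect_false(any(vapply(negT, function(t)
    any(t >= c(100, 200, 300) & t < c(110, 210, 310)), logical(1))))
})

test_that("session inclusion needs at least five behavior epochs", {
  ep5 <- BehaviorEpochs(rep("eat", 5), seq(0, 40, 10), seq(5, 45, 10))
  ep4 <- BehaviorEpochs(rep("eat", 4), seq(0, 30, 10), seq(5, 35, 10))
  expect_true(sessionInclusion(ep5, "eat"))
  expect_false(sessionInclusion(ep4, "eat"))
  expect_false(sessionInclusion(BehaviorEpochs(), "eat"))
})

test_that("decoding hits its limits on separable and uninformative data", {
  set.seed(20)
  n <- 400
  tt <- seq(0.5, 400, by = 1)
  labs <- rep(c("behavior", "non"), n / 2)
  sep <- cbind(as.numeric(labs == "behavior") + rnorm(n, 0, 0.01), rnorm(n))
  dsSep <- new("DecodingDataset", features = sep, label = labs, time = tt,
               behavior = "eat")
  expect_equal(crossvalDecode(dsSep, seed = 1)@meanAccuracy, 1)
  # identical feature distribution across classes: near chance
  dsNull <- new("DecodingDataset",
                features = matrix(rnorm(n * 5), n), label = labs,
                time = tt, behavior = "eat")
  accNull <- crossvalDecode(dsNull, seed = 1)@meanAccuracy
  expect_gt(accNull, 0.3)
  expect_lt(accNull, 0.7)
})

test_that("planted approach ensembles decode above a permutation null", {
  cfg <- generatorConfig(nCells = 40, duration = 900,
                         fractions = c(eatNeg = 0, eatPos = 0,
                                       approachPos = 0.5, unmod = 0.5))
  ses <- generateSession(cfg, seed = 31)
  ds <- buildDecodingDataset(ses@traces, ses@epochs, "approach", seed = 1)
  obs <- crossvalDecode(ds, seed = 1)@meanAccuracy
  null <- vapply(1:19, function(s) {
    ep <- shuffleEpochOnsets(ses@epochs, "approach", cfg$duration,
                             seed = 500 + s)
    dsN <- buildDecodingDataset(ses@traces, ep, "approach", seed = s)
    crossvalDecode(dsN, seed = s)@meanAccuracy
  }, numeric(1))
  expect_gt(obs, stats::quantile(null, 0.95))
})

test_that("the behavior coefficient equals the group mean difference", {
  set.seed(2)
  ind <- rep(c(0, 1), each = 200)
  expect_equal(fitBehaviorGlm(ind, ind), 1)
  x <- rnorm(400)
  expect_lt(abs(fitBehaviorGlm(x, ind)), 0.3)
  for (rep in 1:20) {
    tr <- rnorm(300)
    ii <- rbinom(300, 1, 0.3)
    if (length(unique(ii)) < 2) next
    expect_equal(fitBehaviorGlm(tr, ii),
                 mean(tr[ii == 1]) - mean(tr[ii == 0]), tolerance = 1e-12)
  }
  expect_error(fitBehaviorGlm(x, rep(1, 400)), "constant")
})

test_that("onset randomization preserves durations and bounds", {
  ep <- BehaviorEpochs(rep("eat", 4), c(10, 30, 50, 70), c(20, 38, 60, 81))
  tr <- rnorm(1000)
  null <- bootstrapOnsetNull(tr, ep, "eat", rate = 10, nShuffles = 50,
                             seed = 3)
  expect_length(null, 50)
  expect_identical(null,
                   bootstrapOnsetNull(tr, ep, "eat", rate = 10,
                                      nShuffles = 50, seed = 3))
  # epochs covering the whole session leave no placement freedom
  full <- BehaviorEpochs("eat", 0, 100)
  expect_error(bootstrapOnsetNull(tr, full, "eat", rate = 10), "freedom")
  # shuffled schedules stay inside the session and keep durations
  starts <- withr::with_seed(4, FeedScope:::.randomizeOnsets(c(5, 8, 2), 60))
  expect_true(all(starts >= 0))
  expect_true(all(starts + c(5, 8, 2) <= 60))
  expect_true(all(diff(starts) >= c(5, 8)[1:2] - 1e-9))
})

test_that("observed coefficients of noise traces sit inside their null", {
  # coverage calibration: central 90% of the null should contain the
  # observed coefficient about 90% of the time
  covered <- vapply(1:80, function(s) {
    set.seed(s + 900)
    tr <- rnorm(600)
    ep <- BehaviorEpochs(rep("eat", 5), seq(5, 85, 20), seq(12, 92, 20))
    beta <- fitBehaviorGlm(tr, FeedScope:::.behaviorIndicator(
      epochTable(ep), (seq_along(tr) - 1) / 5))
    null <- bootstrapOnsetNull(tr, ep, "eat", rate = 5, nShuffles = 60,
                               seed = s)
    beta > stats::quantile(null, 0.05) && beta < stats::quantile(null, 0.95)
  }, logical(1))
  expect_gt(mean(covered), 0.78)
  expect_lt(mean(covered), 0.98)
})

test_that("cell classification follows the 95% bootstrap rule", {
  null <- seq(-1, 1, length.out = 100)
  expect_equal(classifyCell(2, null)$class, "+")
  expect_equal(classifyCell(-2, null)$class, "-")
  expect_equal(classifyCell(0, null)$class, "ns")
  # beta strictly above 95 of 100 values is "+" ...
  expect_equal(classifyCell(0.5, c(rep(0, 95), rep(1, 5)))$class, "+")
  expect_equal(classifyCell(1, c(rep(0, 95), rep(1, 5)))$class, "+")
  # ... but exact ties do not count toward the exceeded fraction
  expect_equal(classifyCell(1, c(rep(0, 94), rep(1, 6)))$class, "ns")
})

test_that("classifyCells recovers planted eat- cells", {
  cfg <- generatorConfig(nCells = 30, duration = 1200,
                         fractions = c(eatNeg = 0.5, eatPos = 0,
                                       approachPos = 0, unmod = 0.5))
  ses <- generateSession(cfg, seed = 41)
  cl <- classifyCells(ses@traces, ses@epochs, "eat", nShuffles = 100,
                      seed = 42)
  truth <- groundTruth(ses)@cellType
  expect_gte(mean(cl$class[truth == "eatNeg"] == "-"), 0.8)
  expect_identical(cl, classifyCells(ses@traces, ses@epochs, "eat",
                                     nShuffles = 100, seed = 42))
  # the joint fit equals the per-cell GLM route
  ind <- FeedScope:::.behaviorIndicator(
    epochTable(ses@epochs)[epochTable(ses@epochs)$label == "eat", ],
    sampleTimes(ses@traces))
  betas <- apply(traceValues(ses@traces), 1, fitBehaviorGlm,
                 indicator = ind)
  expect_equal(cl$beta, unname(betas), tolerance = 1e-12)
})

test_that("weight correlations track shared and independent ensembles", {
  beta <- c(a = 0.5, b = -0.2, c = 1.4, d = 0.1, e = -0.9)
  map <- CoRegistrationMap(names(beta), names(beta))
  expect_equal(weightCorrelation(beta, beta, map)$rho, 1)
  expect_equal(weightCorrelation(beta, -beta, map)$rho, -1)
  expect_error(weightCorrelation(beta[1:2], beta[1:2],
                                 CoRegistrationMap(c("a", "b"), c("a", "b"))),
               "3 mapped")
  # synthetic pair with shared eat ensembles only
  pair <- generateAssayPair(generatorConfig(nCells = 60, duration = 900),
                            overlap = "eat", dropout = 0, seed = 77)
  betaOf <- function(ses, beh) {
    df <- epochTable(ses@epochs)
    ind <- FeedScope:::.behaviorIndicator(df[df$label == beh, ],
                                          sampleTimes(ses@traces))
    b <- apply(traceValues(ses@traces), 1, fitBehaviorGlm, indicator = ind)
    names(b) <- cellIds(ses@traces)
    b
  }
  mp <- pair$map
  wEat <- weightCorrelation(betaOf(pair$sessionA, "eat"),
                            betaOf(pair$sessionB, "eat"), mp)
  wApp <- weightCorrelation(betaOf(pair$sessionA, "approach"),
                            betaOf(pair$sessionB, "approach"), mp)
  expect_gt(wEat$rho, 0.5)
  expect_lt(wEat$p, 1e-4)
  expect_lt(abs(wApp$rho), 0.35)
})

test_that("profile correlations and the Fisher comparison behave", {
  set.seed(6)
  tm <- TraceMatrix(matrix(rnorm(3 * 600), 3), c("a", "b", "c"), rate = 7.5)
  tens <- alignToEvents(tm, c(20, 40, 60), c(3, 3))
  expect_equal(profileCorrelation(tens, tens, c("a", "b"))$rho, 1)
  expect_equal(fisherRToZ(0.4, 0.4, 30, 30)$z, 0)
  expect_equal(fisherRToZ(0.4, 0.4, 30, 30)$p, 1)
  got <- fisherRToZ(0.8, 0.2, 50, 50)
  zOracle <- (atanh(0.8) - atanh(0.2)) / sqrt(1 / 47 + 1 / 47)
  expect_equal(got$z, zOracle, tolerance = 1e-12)
  expect_error(fisherRToZ(0.5, 0.5, 3, 30), "exceed 3")
  tmB <- TraceMatrix(matrix(rnorm(3 * 600), 3), c("a", "b", "c"), rate = 7.5)
  tensB <- alignToEvents(tmB, c(20, 40, 60), c(2, 2))
  expect_error(profileCorrelation(tens, tensB, "a"), "offset grid")
})

test_that("decoding accuracy grows with the planted effect size", {
  acc <- vapply(c(1.2, 2, 4), function(mult) {
    mean(vapply(1:4, function(s) {
      cfg <- generatorConfig(nCells = 30, duration = 900, eatPosMult = mult,
                             fractions = c(eatNeg = 0, eatPos = 0.5,
                                           approachPos = 0, unmod = 0.5))
      ses <- generateSession(cfg, seed = 600 + s)
      ds <- buildDecodingDataset(ses@traces, ses@epochs, "eat", seed = s)
      crossvalDecode(ds, seed = s)@meanAccuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) > -0.02))  # monotone up to seed noise
  expect_gt(acc[3], acc[1])
})
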