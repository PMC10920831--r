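## Pipeline orchestration and statistics: nonparametric paired/unpaired
## comparisons, one-sample t-tests, BH false-discovery-rate adjustment, and
## the end-to-end synthetic pipeline report.

#' Pipeline configuration
#'
#' Thresholds and generator settings for [runPipeline()]. Defaults are the
#' analysis constants: 10-cm minimum approach decrease, 2-cm/s minimum
#' approach speed, 2-s post-onset decoding window, 0.95 classification
#' quantile, 100 bootstrap shuffles, 5 decoding folds, 10-s train/test gap,
#' 5-epoch session inclusion, and a 0.10 variance-filter fraction.
#'
#' @param generator a [generatorConfig()].
#' @param overlap behaviors shared across the synthetic assay pair.
#' @param dropout co-registration pair dropout fraction.
#' @param minDecrease,minSpeed approach-detection thresholds (cm, cm/s).
#' @param windowAfterOnset decoding positive window (s).
#' @param quantile bootstrap classification quantile.
#' @param nShuffles bootstrap iterations.
#' @param kFolds decoding folds.
#' @param minGap decoding train/test gap (s).
#' @param minCount session-inclusion epoch count.
#' @param varianceFraction variance-filter fraction.
#' @param nSilhouetteShuffles permutations for the silhouette chance level.
#' @param seed master seed; every random stage derives from it.
#' @return a validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(generator = generatorConfig(),
                           overlap = "eat",
                           dropout = 0.1,
                           minDecrease = 10,
                           minSpeed = 2,
                           windowAfterOnset = 2,
                           quantile = 0.95,
                           nShuffles = 100,
                           kFolds = 5,
                           minGap = 10,
                           minCount = 5,
                           varianceFraction = 0.10,
                           nSilhouetteShuffles = 200,
                           seed = 1) {
  cfg <- as.list(environment())
  num <- cfg[c("minDecrease", "minSpeed", "windowAfterOnset", "quantile",
               "nShuffles", "kFolds", "minGap", "minCount",
               "varianceFraction")]
  if (any(unlist(num) <= 0)) stop("all thresholds must be positive")
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Nonparametric and one-sample comparisons
#'
#' Two-tailed Wilcoxon signed-rank (paired) or rank-sum (unpaired)
#' comparison, with exact small-sample p-values for n <= 25 and the normal
#' approximation above, or a one-sample two-tailed t-test of `x` against the
#' constant `mu` when `y` is omitted.
#'
#' @param x,y numeric samples (`y = NULL` for the one-sample t-test).
#' @param paired logical; paired samples must have equal length.
#' @param mu constant for the one-sample t-test.
#' @param name label carried into the result.
#' @return a `StatResult` data.frame row: `test`, `statistic`, `z`, `p`,
#'   `n1`, `n2`, `flag`.
#' @export
pairedAndUnpairedTests <- function(x, y = NULL, paired = FALSE, mu = 0,
                                   name = NULL) {
  res <- function(test, statistic, z, p, n1, n2, flag = "") {
    data.frame(test = if (is.null(name)) test else name,
               statistic = statistic, z = z, p = min(1, p),
               n1 = n1, n2 = n2, flag = flag, stringsAsFactors = FALSE)
  }
  if (is.null(y)) {
    if (length(x) < 2L) stop("need n >= 2")
    tt <- stats::t.test(x, mu = mu)
    return(res("one-sample t", unname(tt$statistic), NA_real_, tt$p.value,
               length(x), 0L))
  }
  if (paired) {
    if (length(x) != length(y)) stop("paired samples need equal lengths")
    d <- x - y
    if (all(d == 0))
      return(res("wilcoxon signed-rank", 0, 0, 1, length(x), length(y),
                 flag = "all-zero differences"))
    exact <- sum(d != 0) <= 25 && !any(duplicated(abs(d[d != 0])))
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = exact))
    dd <- d[d != 0]
    r <- rank(abs(dd))
    w <- sum(r[dd > 0])
    nn <- length(dd)
    z <- (w - nn * (nn + 1) / 4) /
      sqrt(nn * (nn + 1) * (2 * nn + 1) / 24)
    return(res("wilcoxon signed-rank", unname(wt$statistic), z, wt$p.value,
               length(x), length(y)))
  }
  exact <- length(x) <= 25 && length(y) <= 25 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  z <- (w - n1 * (n1 + n2 + 1) / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  res("wilcoxon rank-sum", unname(wt$statistic), z, wt$p.value, n1, n2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value family; monotone in
#' the input p-values.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param family optional family name attached as an attribute.
#' @return numeric q-values.
#' @export
fdrAdjust <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  if (!is.null(family)) attr(q, "family") <- family
  q
}

# one session's derived pieces: epochs re-derived from pose + planted eat,
# filtered traces, labels on the trace grid
.prepareSession <- function(ses, cfg) {
  planted <- epochTable(ses@epochs)
  approach <- detectApproach(ses@pose, cfg$minDecrease, cfg$minSpeed)
  rear <- detectRearing(ses@pose)
  eat <- planted[planted$label == "eat", , drop = FALSE]
  epochs <- BehaviorEpochs(rbind(eat, epochTable(approach),
                                 epochTable(rear)))
  vf <- varianceFilter(ses@traces, cfg$varianceFraction)
  labels <- rasterizeEpochs(epochs, sampleTimes(vf$traces))
  list(epochs = epochs, traces = vf$traces, excluded = vf$excluded,
       labels = labels)
}

#' Run the full synthetic-session pipeline
#'
#' Generates a co-registered assay pair, re-derives approach and rearing
#' epochs from the pose (eating epochs are taken from the session's epoch
#' table, as they come from manual scoring), filters cells by variance, and
#' runs the population-geometry, decoding and cell-classification analyses
#' with their statistics. All randomness derives from `config$seed`.
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional directory for tabular outputs, a machine-readable
#'   JSON result file and a plain-text log.
#' @return list with `silhouette`, `decoding`, `classification`,
#'   `conservation`, `correlations`, `stats` (the declared test families
#'   with q-values) and `log`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  cfg <- config
  pair <- tryCatch(
    generateAssayPair(cfg$generator, cfg$overlap, cfg$dropout, cfg$seed),
    error = function(e) stop("stage synth failed: ", conditionMessage(e)))
  seeds <- withr::with_seed(cfg$seed + 1,
                            sample.int(.Machine$integer.max - 1L, 8L))
  sessions <- list(A = pair$sessionA, B = pair$sessionB)
  prep <- lapply(names(sessions), function(nm)
    tryCatch(.prepareSession(sessions[[nm]], cfg),
             error = function(e)
               stop("stage behavior/traces failed for session ", nm, ": ",
                    conditionMessage(e))))
  names(prep) <- names(sessions)

  # per-session geometry: silhouette of the PC embedding + permutation chance
  silh <- lapply(seq_along(prep), function(i) {
    p <- prep[[i]]
    emb <- embedPCA(p$traces, p$labels)
    # cap samples entering the permutation null to keep it tractable
    if (nrow(embeddingScores(emb)) > 1500L) {
      idx <- withr::with_seed(seeds[i] + 1,
        sort(sample(nrow(embeddingScores(emb)), 1500L)))
      emb <- new("ClusterEmbedding",
                 scores = embeddingScores(emb)[idx, , drop = FALSE],
                 labels = sampleLabels(emb)[idx],
                 assay = character(),
                 explainedVar = explainedVariance(emb),
                 loadings = emb@loadings)
    }
    ch <- chanceSilhouette(emb, cfg$nSilhouetteShuffles, seeds[i])
    list(observed = ch$observed, chanceMean = mean(ch$null),
         percentile = ch$percentile,
         explainedVar = explainedVariance(emb))
  })
  names(silh) <- names(prep)

  # decoding per session and behavior
  decoding <- list()
  for (nm in names(prep)) {
    p <- prep[[nm]]
    for (beh in c("approach", "eat")) {
      if (!sessionInclusion(p$epochs, beh, cfg$minCount)) next
      ds <- buildDecodingDataset(p$traces, p$epochs, beh,
                                 cfg$windowAfterOnset, seeds[3L])
      dr <- crossvalDecode(ds, cfg$kFolds, cfg$minGap, seeds[4L])
      decoding[[paste(nm, beh, sep = ".")]] <-
        list(meanAccuracy = dr@meanAccuracy, foldAccuracy = dr@foldAccuracy,
             chance = dr@chance)
    }
  }

  # bootstrap GLM classification per session and behavior
  classification <- list()
  for (i in seq_along(prep)) {
    p <- prep[[i]]
    for (beh in c("approach", "eat")) {
      cl <- classifyCells(p$traces, p$epochs, beh, cfg$nShuffles,
                          cfg$quantile, seeds[4L + i])
      classification[[paste(names(prep)[i], beh, sep = ".")]] <- cl
    }
  }
  countsOf <- function(cl) table(factor(cl$class, c("+", "-", "ns")))

  # cross-assay conservation over co-registered cells (full neural space)
  trA <- prep$A$traces; trB <- prep$B$traces
  pr <- coregPairs(pair$map)
  pr <- pr[pr$idA %in% cellIds(trA) & pr$idB %in% cellIds(trB), ,
           drop = FALSE]
  conservation <- NULL
  if (nrow(pr) >= 3L) {
    joint <- concatenateCoregistered(trA, trB, CoRegistrationMap(pr))
    jointLabels <- c(prep$A$labels, prep$B$labels)
    dEat <- crossAssayDistances(joint$traces, jointLabels, joint$assay, "eat")
    dApp <- crossAssayDistances(joint$traces, jointLabels, joint$assay,
                                "approach")
    ct <- conservationTest(dEat, dApp)
    conservation <- list(test = ct,
                         medianEat = stats::median(dEat),
                         medianApproach = stats::median(dApp),
                         direction = if (ct$moreConserved == "eat")
                           "eat more conserved" else "approach more conserved")
  }

  # cross-assay weight and activity-profile correlations
  correlations <- NULL
  if (nrow(pr) >= 3L) {
    betaOf <- function(cl) stats::setNames(cl$beta, cl$cellId)
    wEat <- weightCorrelation(betaOf(classification$A.eat),
                              betaOf(classification$B.eat), pair$map)
    wApp <- weightCorrelation(betaOf(classification$A.approach),
                              betaOf(classification$B.approach), pair$map)
    eatOnsetsA <- epochTable(prep$A$epochs)
    eatOnsetsA <- eatOnsetsA$start[eatOnsetsA$label == "eat"]
    eatOnsetsB <- epochTable(prep$B$epochs)
    eatOnsetsB <- eatOnsetsB$start[eatOnsetsB$label == "eat"]
    tensA <- alignToEvents(trA, eatOnsetsA, c(5, 5), "eat")
    tensB <- alignToEvents(trB, eatOnsetsB, c(5, 5), "eat")
    clA <- classification$A.eat
    profOf <- function(cls) {
      cells <- intersect(clA$cellId[clA$class == cls], pr$idA)
      if (length(cells) < 2L) return(NULL)
      profileCorrelation(tensA, tensB, cells)
    }
    pNeg <- profOf("-"); pPos <- profOf("+")
    fisher <- if (!is.null(pNeg) && !is.null(pPos))
      fisherRToZ(pNeg$rho, pPos$rho, pNeg$n, pPos$n) else NULL
    correlations <- list(eatWeights = wEat, approachWeights = wApp,
                         profileEatNeg = pNeg, profileEatPos = pPos,
                         profileComparison = fisher)
  }

  # declared test families with BH adjustment
  fam <- data.frame(test = character(), p = numeric(),
                    stringsAsFactors = FALSE)
  addFam <- function(fam, test, p) rbind(fam, data.frame(test = test, p = p))
  if (!is.null(conservation))
    fam <- addFam(fam, "conservation.eat_vs_approach", conservation$test$p)
  if (!is.null(correlations)) {
    fam <- addFam(fam, "weights.eat", correlations$eatWeights$p)
    fam <- addFam(fam, "weights.approach", correlations$approachWeights$p)
  }
  if (nrow(fam)) fam$q <- fdrAdjust(fam$p, family = "cross-assay")

  out <- list(
    silhouette = silh,
    decoding = decoding,
    classificationCounts = lapply(classification, countsOf),
    classification = classification,
    conservation = conservation,
    correlations = correlations,
    stats = fam,
    log = c(sprintf("seed: %d", cfg$seed),
            sprintf("cells kept A/B: %d/%d", nCells(trA), nCells(trB)),
            sprintf("co-registered pairs: %d", nrow(pr))))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    machine <- list(
      silhouette = lapply(silh, function(s)
        s[c("observed", "chanceMean", "percentile")]),
      decoding = lapply(decoding, function(d)
        d[c("meanAccuracy", "chance")]),
      classificationCounts = lapply(out$classificationCounts,
                                    function(tt) as.list(as.integer(tt))),
      conservation = if (is.null(conservation)) NULL else
        list(medianEat = conservation$medianEat,
             medianApproach = conservation$medianApproach,
             p = conservation$test$p, z = conservation$test$z,
             direction = conservation$direction),
      stats = fam)
    jsonlite::write_json(machine, file.path(outDir, "results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    for (nm in names(classification))
      utils::write.csv(classification[[nm]],
                       file.path(outDir, paste0("cells_", nm, ".csv")),
                       row.names = FALSE)
    if (nrow(fam))
      utils::write.csv(fam, file.path(outDir, "stats.csv"),
                       row.names = FALSE)
    writeLines(c(out$log, paste("written:", format(Sys.time()))),
               file.path(outDir, "run.log"))
  }
  out
}
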