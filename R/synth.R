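## Synthetic feeding-session generator with planted ground truth: a behavior
## epoch schedule, a pose track that physically realizes it, behavior-
## modulated Poisson event traces convolved with a calcium kernel, and
## dual-channel photometry with a shared motion artifact.

#' Generator configuration
#'
#' All tunable parameters of the synthetic-session generator. Defaults
#' describe a 30-minute feeding session: pose tracked at 30 samples/s,
#' traces at 7.5 samples/s (30 frames/s video temporally downsampled by
#' four), a circular 30-cm-radius arena with the food target at its center,
#' repeated approach (net decrease > 10 cm at > 2 cm/s) and eating bouts,
#' and a GCaMP6s-like double-exponential calcium kernel.
#'
#' @param nCells number of cells (>= 1).
#' @param duration session duration (s, > 0).
#' @param behaviorRate pose sampling rate (samples/s).
#' @param traceRate trace sampling rate (samples/s).
#' @param fractions named fractions of `eatNeg`, `eatPos`, `approachPos` and
#'   `unmod` cells; must sum to 1.
#' @param eatNegMult,eatPosMult,approachPosMult rate multipliers applied to
#'   the respective cell types during their behavior (dimensionless, >= 0).
#' @param baseRate baseline event rate (events/s).
#' @param tauRise,tauDecay calcium kernel time constants (s).
#' @param noiseSd additive Gaussian trace noise (df/F).
#' @param arenaRadius circular arena radius (cm); food target at the center.
#' @param approachStartDist,approachEndDist head-to-target distance (cm) at
#'   approach start/end.
#' @param approachDuration approach bout duration (s).
#' @param eatDurationRange range (s) of eating bout durations.
#' @param itiRange range (s) of inter-trial intervals.
#' @param rearProb probability of a rearing bout in a long inter-trial
#'   interval.
#' @param rearDuration rearing bout duration (s).
#' @param poseJitterSd tracking jitter added to all pose samples (cm).
#' @param photometryRate,photometryDuration photometry sampling rate
#'   (samples/s) and duration (s).
#' @param photometryBaselineSig,photometryBaselineRef channel baselines
#'   (a.u.).
#' @param photometryTransientAmplitude amplitude of behavior-locked
#'   transients (a.u.).
#' @param photometryNoiseSd channel noise sd (a.u.).
#' @return a validated list of class `GeneratorConfig`.
#' @export
generatorConfig <- function(nCells = 50,
                            duration = 1800,
                            behaviorRate = 30,
                            traceRate = 7.5,
                            fractions = c(eatNeg = 0.4, eatPos = 0.15,
                                          approachPos = 0.2, unmod = 0.25),
                            eatNegMult = 0.2,
                            eatPosMult = 3,
                            approachPosMult = 3,
                            baseRate = 0.5,
                            tauRise = 0.2,
                            tauDecay = 1.5,
                            noiseSd = 0.05,
                            arenaRadius = 30,
                            approachStartDist = 22,
                            approachEndDist = 1,
                            approachDuration = 6,
                            eatDurationRange = c(8, 12),
                            itiRange = c(14, 24),
                            rearProb = 0.6,
                            rearDuration = 3,
                            poseJitterSd = 0.02,
                            photometryRate = 20,
                            photometryDuration = 500,
                            photometryBaselineSig = 2,
                            photometryBaselineRef = 1,
                            photometryTransientAmplitude = 0.3,
                            photometryNoiseSd = 0.01) {
  cfg <- as.list(environment())
  if (cfg$nCells < 1) stop("nCells must be >= 1")
  if (cfg$duration <= 0) stop("duration must be positive")
  if (cfg$behaviorRate <= 0 || cfg$traceRate <= 0 || cfg$photometryRate <= 0)
    stop("sampling rates must be positive")
  need <- c("eatNeg", "eatPos", "approachPos", "unmod")
  if (!all(need %in% names(cfg$fractions)))
    stop("fractions must name ", paste(need, collapse = ", "))
  if (any(cfg$fractions < 0))
    stop("fractions must be non-negative")
  if (abs(sum(cfg$fractions) - 1) > 1e-9)
    stop("cell-type fractions must sum to 1 (got ", sum(cfg$fractions), ")")
  if (cfg$eatNegMult < 0 || cfg$eatPosMult < 0 || cfg$approachPosMult < 0)
    stop("rate multipliers must be >= 0")
  if (cfg$baseRate < 0) stop("baseRate must be >= 0")
  if (cfg$noiseSd < 0) stop("noiseSd must be >= 0")
  if (cfg$tauRise >= cfg$tauDecay)
    stop("tauRise must be smaller than tauDecay")
  class(cfg) <- c("GeneratorConfig", "list")
  cfg
}

# per-cell type and rate-multiplier matrix (columns approach/eat/rear)
.drawModulation <- function(cfg) {
  type <- sample(c("eatNeg", "eatPos", "approachPos", "unmod"),
                 cfg$nCells, replace = TRUE,
                 prob = cfg$fractions[c("eatNeg", "eatPos", "approachPos",
                                        "unmod")])
  m <- matrix(1, cfg$nCells, 3,
              dimnames = list(paste0("cell_", seq_len(cfg$nCells)),
                              c("approach", "eat", "rear")))
  m[type == "eatNeg", "eat"] <- cfg$eatNegMult
  m[type == "eatPos", "eat"] <- cfg$eatPosMult
  m[type == "approachPos", "approach"] <- cfg$approachPosMult
  list(modulation = m, type = type)
}

# trial-structured epoch schedule: approach -> eat, rear in long ITIs
.makeSchedule <- function(cfg) {
  label <- character(); start <- numeric(); end <- numeric()
  angle <- numeric()  # approach direction, consumed by the pose realizer
  rearAt <- numeric()
  th <- stats::runif(1, 0, 2 * pi)
  t <- 5
  repeat {
    eDur <- stats::runif(1, cfg$eatDurationRange[1L], cfg$eatDurationRange[2L])
    if (t + cfg$approachDuration + eDur + 5 > cfg$duration) break
    label <- c(label, "approach", "eat")
    start <- c(start, t, t + cfg$approachDuration)
    end <- c(end, t + cfg$approachDuration, t + cfg$approachDuration + eDur)
    angle <- c(angle, th)
    tEnd <- t + cfg$approachDuration + eDur
    iti <- stats::runif(1, cfg$itiRange[1L], cfg$itiRange[2L])
    th <- th + stats::runif(1, -0.6, 0.6)
    doRear <- iti >= 20 && stats::runif(1) < cfg$rearProb &&
      tEnd + 13 <= cfg$duration
    if (doRear) {
      label <- c(label, "rear")
      start <- c(start, tEnd + 10)
      end <- c(end, tEnd + 10 + cfg$rearDuration)
      rearAt <- c(rearAt, tEnd + 10)
    } else {
      rearAt <- c(rearAt, NA_real_)
    }
    t <- tEnd + iti
  }
  sched <- data.frame(label = label, start = start, end = end,
                      stringsAsFactors = FALSE)
  attr(sched, "angle") <- angle
  attr(sched, "rearAt") <- rearAt
  sched
}

# head path physically realizing the schedule, then body parts around it
.makePose <- function(cfg, sched) {
  dt <- 1 / cfg$behaviorRate
  tt <- seq(0, cfg$duration - dt / 2, by = dt)
  ap <- sched[sched$label == "approach", , drop = FALSE]
  angle <- attr(sched, "angle")
  rearAt <- attr(sched, "rearAt")
  ring <- function(r, th) c(r * cos(th), r * sin(th))
  wx <- numeric(); wy <- numeric(); wt <- numeric()
  addW <- function(t, p) {
    wt <<- c(wt, t); wx <<- c(wx, p[1L]); wy <<- c(wy, p[2L])
  }
  addW(0, ring(cfg$approachStartDist,
               if (length(angle)) angle[1L] else 0))
  for (i in seq_len(nrow(ap))) {
    a0 <- ap$start[i]
    a1 <- ap$end[i]
    eatRow <- sched[sched$label == "eat" & abs(sched$start - a1) < 1e-9, ]
    e1 <- eatRow$end[1L]
    addW(a0, ring(cfg$approachStartDist, angle[i]))
    addW(a1, ring(cfg$approachEndDist, angle[i]))
    addW(e1, ring(cfg$approachEndDist, angle[i]))   # hold at target while eating
    thNext <- if (i < nrow(ap)) angle[i + 1L] else angle[i]
    nextStart <- if (i < nrow(ap)) ap$start[i + 1L] else cfg$duration
    if (!is.na(rearAt[i]) && rearAt[i] + cfg$rearDuration < nextStart) {
      r0 <- rearAt[i]; r1 <- r0 + cfg$rearDuration
      wall <- ring(cfg$arenaRadius - 1, thNext)
      addW(r0, wall)
      addW(r1, wall)
      addW(min(nextStart, r1 + 6), ring(cfg$approachStartDist, thNext))
    } else {
      iti <- nextStart - e1
      addW(e1 + 0.6 * iti, ring(cfg$approachStartDist, thNext))
    }
  }
  if (wt[length(wt)] < cfg$duration)
    addW(cfg$duration, c(wx[length(wx)], wy[length(wy)]))
  hx <- stats::approx(wt, wx, xout = tt, rule = 2)$y
  hy <- stats::approx(wt, wy, xout = tt, rule = 2)$y
  hx <- hx + stats::rnorm(length(tt), 0, cfg$poseJitterSd)
  hy <- hy + stats::rnorm(length(tt), 0, cfg$poseJitterSd)
  # heading from smoothed displacement; carried forward when stationary
  dxs <- c(diff(hx), 0); dys <- c(diff(hy), 0)
  sp <- sqrt(dxs^2 + dys^2)
  ux <- dxs / pmax(sp, 1e-9); uy <- dys / pmax(sp, 1e-9)
  still <- sp < 1e-6
  if (any(!still)) {
    lastIdx <- cummax(ifelse(still, 0L, seq_along(sp)))
    lastIdx[lastIdx == 0L] <- which(!still)[1L]
    ux <- ux[lastIdx]; uy <- uy[lastIdx]
  }
  head <- cbind(hx, hy)
  px <- -uy; py <- ux  # perpendicular
  parts <- list(
    nose = head + cbind(ux, uy) * 1.0,
    earL = head + cbind(px, py) * 0.8,
    earR = head - cbind(px, py) * 0.8,
    tailbase = head - cbind(ux, uy) * 3.0)
  PoseTrack(time = tt, parts = parts,
            target = matrix(0, length(tt), 2),
            arena = list(shape = "circular", center = c(0, 0),
                         radius = cfg$arenaRadius),
            rate = cfg$behaviorRate)
}

# GCaMP-like double-exponential kernel sampled at the trace rate, peak 1
.calciumKernel <- function(cfg) {
  ts <- seq(0, 6 * cfg$tauDecay, by = 1 / cfg$traceRate)
  k <- exp(-ts / cfg$tauDecay) - exp(-ts / cfg$tauRise)
  k / max(k)
}

# Poisson event counts per trace bin, rate = baseRate * multiplier(label)
.makeTraces <- function(cfg, modulation, sched) {
  nT <- round(cfg$duration * cfg$traceRate)
  ttT <- (seq_len(nT) - 1L) / cfg$traceRate
  lab <- rasterizeEpochs(BehaviorEpochs(sched), ttT)
  mult <- matrix(1, nrow(modulation), nT)
  for (l in colnames(modulation)) {
    sel <- lab == l
    if (any(sel)) mult[, sel] <- modulation[, l]
  }
  lambda <- cfg$baseRate * mult / cfg$traceRate
  counts <- matrix(stats::rpois(length(lambda), lambda),
                   nrow(modulation), nT)
  k <- .calciumKernel(cfg)
  L <- length(k)
  padded <- rbind(matrix(0, L - 1L, nrow(counts)), t(counts))
  conv <- stats::filter(padded, k, sides = 1)
  clean <- t(conv[L:(L - 1L + nT), , drop = FALSE])
  noisy <- clean + matrix(stats::rnorm(length(clean), 0, cfg$noiseSd),
                          nrow(clean), ncol(clean))
  list(values = noisy, counts = counts)
}

#' Generate one complete synthetic session
#'
#' Draws per-cell behavior modulation, an approach/eat/rear epoch schedule, a
#' pose track that physically realizes it (moving toward the target during
#' approach, staying at the target during eating, head near the wall during
#' rearing), and trace matrices built from behavior-modulated Poisson event
#' trains convolved with the calcium kernel plus Gaussian noise. Identical
#' `(config, seed)` give byte-identical output.
#'
#' @param config a [generatorConfig()].
#' @param seed integer seed.
#' @param modulation optional pre-drawn cells x labels multiplier matrix
#'   (with attribute handling left to [generateAssayPair()]).
#' @param cellType optional per-cell type vector matching `modulation`.
#' @return a [SessionBundle-class].
#' @export
generateSession <- function(config, seed = 1, modulation = NULL,
                            cellType = NULL) {
  if (!inherits(config, "GeneratorConfig"))
    config <- do.call(generatorConfig, config)
  withr::with_seed(seed, {
    if (is.null(modulation)) {
      dm <- .drawModulation(config)
      modulation <- dm$modulation
      cellType <- dm$type
    }
    sched <- .makeSchedule(config)
    pose <- .makePose(config, sched)
    tr <- .makeTraces(config, modulation, sched)
    truth <- new("GroundTruth", modulation = modulation,
                 cellType = cellType, sharedLabels = character(),
                 schedule = as.data.frame(sched), events = tr$counts,
                 seed = as.numeric(seed),
                 kernelTauRise = config$tauRise,
                 kernelTauDecay = config$tauDecay,
                 noiseSd = config$noiseSd, baseRate = config$baseRate)
    new("SessionBundle", pose = pose, epochs = BehaviorEpochs(sched),
        traces = TraceMatrix(tr$values, rownames(modulation),
                             config$traceRate),
        truth = truth)
  })
}

#' Generate a co-registered pair of synthetic assays
#'
#' Two sessions over the same cells. For behaviors in `overlap` the per-cell
#' rate multipliers are identical across the pair (a shared ensemble); for
#' all other behaviors they are drawn independently. The co-registration map
#' pairs every cell with itself, thinned by `dropout`.
#'
#' @param config a [generatorConfig()].
#' @param overlap behaviors whose encoding is shared across the pair
#'   (subset of approach/eat/rear; default `"eat"`).
#' @param dropout fraction of cell pairs lost from the map, in \[0, 1\].
#' @param seed integer seed.
#' @return list with `sessionA`, `sessionB` ([SessionBundle-class]) and
#'   `map` ([CoRegistrationMap-class]).
#' @export
generateAssayPair <- function(config, overlap = "eat", dropout = 0,
                              seed = 1) {
  if (!inherits(config, "GeneratorConfig"))
    config <- do.call(generatorConfig, config)
  bad <- setdiff(overlap, .BEHAVIOR_LABELS)
  if (length(bad))
    stop("overlap labels outside the behavior vocabulary: ",
         paste(bad, collapse = ", "))
  if (dropout < 0 || dropout > 1) stop("dropout must lie in [0, 1]")
  sub <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 5L))
  modA <- withr::with_seed(sub[1L], .drawModulation(config))
  modB <- withr::with_seed(sub[2L], .drawModulation(config))
  mB <- modB$modulation
  mB[, overlap] <- modA$modulation[, overlap, drop = FALSE]
  sesA <- generateSession(config, sub[3L], modA$modulation, modA$type)
  sesB <- generateSession(config, sub[4L], mB, modB$type)
  sesA@truth@sharedLabels <- as.character(overlap)
  sesB@truth@sharedLabels <- as.character(overlap)
  keep <- withr::with_seed(sub[5L],
    stats::runif(config$nCells) >= dropout)
  ids <- cellIds(sesA@traces)[keep]
  list(sessionA = sesA, sessionB = sesB,
       map = CoRegistrationMap(ids, ids))
}

#' Generate a dual-channel photometry recording with planted structure
#'
#' The 405-nm reference carries the baseline plus a shared low-frequency
#' motion artifact plus noise; the 470-nm signal carries the same artifact
#' plus behavior-locked calcium transients plus noise. The planted artifact,
#' transient series and event times are returned for validation.
#'
#' @param config a [generatorConfig()].
#' @param artifactAmplitude artifact standard deviation (a.u., >= 0).
#' @param seed integer seed.
#' @return list with `recording` ([PhotometryRecording-class]), `artifact`,
#'   `transients` (numeric series) and `eventTimes` (s).
#' @export
generatePhotometry <- function(config, artifactAmplitude = 0.1, seed = 1) {
  if (!inherits(config, "GeneratorConfig"))
    config <- do.call(generatorConfig, config)
  if (artifactAmplitude < 0) stop("artifactAmplitude must be >= 0")
  rate <- config$photometryRate
  if (rate <= 0) stop("sampling rate must be positive")
  n <- round(config$photometryDuration * rate)
  tt <- (seq_len(n) - 1L) / rate
  withr::with_seed(seed, {
    # low-frequency shared artifact: Gaussian-smoothed white noise
    raw <- stats::rnorm(n)
    w <- round(2 * rate)
    gk <- stats::dnorm(seq(-3 * w, 3 * w), sd = w)
    gk <- gk / sum(gk)
    pad <- length(gk)
    sm <- stats::filter(c(rep(0, pad), raw, rep(0, pad)), gk, sides = 2)
    sm <- as.numeric(sm)[(pad + 1L):(pad + n)]
    artifact <- if (artifactAmplitude > 0 && stats::sd(sm) > 0)
      sm / stats::sd(sm) * artifactAmplitude else rep(0, n)
    # behavior-locked transients
    eventTimes <- numeric()
    t <- 10
    while (t < config$photometryDuration - 5) {
      eventTimes <- c(eventTimes, t)
      t <- t + stats::runif(1, 15, 25)
    }
    ts <- seq(0, 6 * config$tauDecay, by = 1 / rate)
    k <- exp(-ts / config$tauDecay) - exp(-ts / config$tauRise)
    k <- k / max(k)
    impulses <- numeric(n)
    idx <- round(eventTimes * rate) + 1L
    impulses[idx[idx >= 1L & idx <= n]] <- 1
    L <- length(k)
    tr <- stats::filter(c(rep(0, L - 1L), impulses), k, sides = 1)
    transients <- as.numeric(tr)[L:(L - 1L + n)] *
      config$photometryTransientAmplitude
    ref <- config$photometryBaselineRef + artifact +
      stats::rnorm(n, 0, config$photometryNoiseSd)
    sig <- config$photometryBaselineSig + artifact + transients +
      stats::rnorm(n, 0, config$photometryNoiseSd)
    list(recording = PhotometryRecording(tt, sig, ref, rate),
         artifact = artifact, transients = transients,
         eventTimes = eventTimes)
  })
}
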