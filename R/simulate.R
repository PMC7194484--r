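## Synthetic-data generators: twin-pair phenotypes under known variance
## components, and full two-channel fTCD sessions with known ground-truth
## laterality. Every generator records its ground truth so pipeline and
## model code can be tested against it.

#' Configuration for the twin-phenotype generator
#'
#' @param nMZ,nDZ pair counts.
#' @param a2,c2 additive-genetic and shared-environment variance
#'   proportions; `e2 = 1 - a2 - c2` must be non-negative.
#' @param marginal `"normal"` (latent scale) or `"jshape"` (fixed monotone
#'   quantile map to a bounded 0-10 handedness-like scale with most mass at
#'   the right-handed end).
#' @param seed integer RNG seed (NULL leaves the RNG state alone).
#' @return validated config list.
#' @export
twinSimConfig <- function(nMZ, nDZ, a2 = 0, c2 = 0,
                          marginal = c("normal", "jshape"), seed = NULL) {
  marginal <- match.arg(marginal)
  e2v <- 1 - a2 - c2
  if (a2 < 0 || c2 < 0 || e2v < -1e-12)
    stop("variance components must be non-negative and sum to at most 1")
  list(nMZ = as.integer(nMZ), nDZ = as.integer(nDZ),
       a2 = a2, c2 = c2, e2 = max(e2v, 0), marginal = marginal, seed = seed)
}

## frozen J-shape quantile map constants (versioned; do not change without
## bumping the package version, tests depend on the mapping being stable)
.JSHAPE_SHAPE1 <- 4
.JSHAPE_SHAPE2 <- 0.8
.JSHAPE_SCALE <- 10

.jshapeMap <- function(z) {
  .JSHAPE_SCALE * qbeta(pnorm(z), .JSHAPE_SHAPE1, .JSHAPE_SHAPE2)
}

## core generator shared with the power simulation (no seed handling)
.simulateTwinCore <- function(nMZ, nDZ, a2, c2, marginal = "normal") {
  e2v <- 1 - a2 - c2
  n <- nMZ + nDZ
  zyg <- rep(c("MZ", "DZ"), c(nMZ, nDZ))
  ## additive genetic: MZ share the whole A factor, DZ share half of it
  aShared <- rnorm(n)
  a1 <- ifelse(zyg == "MZ", aShared,
               sqrt(0.5) * aShared + sqrt(0.5) * rnorm(n))
  a2twin <- ifelse(zyg == "MZ", aShared,
                   sqrt(0.5) * aShared + sqrt(0.5) * rnorm(n))
  cShared <- rnorm(n)
  y1 <- sqrt(a2) * a1 + sqrt(c2) * cShared + sqrt(e2v) * rnorm(n)
  y2 <- sqrt(a2) * a2twin + sqrt(c2) * cShared + sqrt(e2v) * rnorm(n)
  if (marginal == "jshape") {
    y1 <- .jshapeMap(y1)
    y2 <- .jshapeMap(y2)
  }
  TwinPairTable(data.frame(
    familyId = sprintf("fam%04d", seq_len(n)),
    zygosity = zyg, y_1 = y1, y_2 = y2,
    stringsAsFactors = FALSE), phenotypes = "y")
}

#' Simulate twin-pair phenotypes under the ACE model
#'
#' Each pair draws an additive-genetic factor correlated 1 (MZ) or 0.5 (DZ)
#' between twins, a fully shared environment factor and independent
#' nonshared factors; the phenotype is the components' weighted sum
#' `sqrt(a2) A + sqrt(c2) C + sqrt(e2) E` on a unit-variance latent scale.
#' The `"jshape"` marginal applies a fixed strictly monotone quantile map
#' onto a 0-10 handedness-like scale, which preserves all rank-based
#' familial structure.
#'
#' @param cfg a [twinSimConfig()].
#' @return A [TwinPairTable-class] with phenotype `"y"`; the generating
#'   components and seed are attached as `attr(x, "groundTruth")`.
#' @examples
#' tw <- simulateTwinPhenotypes(twinSimConfig(100, 100, a2 = 0.5, seed = 7))
#' @export
simulateTwinPhenotypes <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tab <- .simulateTwinCore(cfg$nMZ, cfg$nDZ, cfg$a2, cfg$c2, cfg$marginal)
  attr(tab, "groundTruth") <-
    list(a2 = cfg$a2, c2 = cfg$c2, e2 = cfg$e2,
         marginal = cfg$marginal, seed = cfg$seed)
  tab
}

#' Configuration for the fTCD session generator
#'
#' Defaults emulate the study paradigm: up to 30 trials, each trial a 12 s
#' silent-viewing period followed by a cue to speak and a 10 s description
#' period; the laterality indices are computed 4-14 s after the cue.
#'
#' @param nTrials number of trials, default 30.
#' @param sampleRate samples/second, default 25.
#' @param heartRate,heartRateSD mean and beat-to-beat SD of the heart rate
#'   in bpm; defaults 95 and 8 (child range).
#' @param baselineVelocity named numeric `c(left=, right=)` baseline
#'   velocities in cm/s.
#' @param pulseAmplitude cardiac pulsatility amplitude in cm/s.
#' @param responseDelta true laterality index in percentage points: the
#'   normalised left-minus-right difference averaged over the period of
#'   interest equals this value in expectation.
#' @param bilateralResponse task-evoked bilateral flow increase (percent)
#'   common to both channels (cancels in the difference).
#' @param responsePeakTime,responseShape gamma-activation-curve peak time
#'   (s after the cue) and shape parameter; the curve returns to baseline
#'   by 17 s.
#' @param noiseSd white-noise SD in cm/s per channel.
#' @param driftCoef,driftSd AR(1) coefficient (per sample) and innovation
#'   SD (cm/s) of the slow drift added to each channel.
#' @param dropoutProb,artifactProb,invalidProb per-trial probabilities of a
#'   prolonged signal dropout, a large-amplitude artifact, or a
#'   behaviourally invalid trial (mutually exclusive per trial).
#' @param interTrial seconds between cues to speak, default 33 (long enough
#'   for non-overlapping -12..18 s epochs).
#' @param seed integer RNG seed.
#' @return validated config list.
#' @export
dopplerSimConfig <- function(nTrials = 30, sampleRate = 25,
                             heartRate = 95, heartRateSD = 8,
                             baselineVelocity = c(left = 55, right = 50),
                             pulseAmplitude = 12,
                             responseDelta = 2,
                             bilateralResponse = 3,
                             responsePeakTime = 7, responseShape = 3,
                             noiseSd = 1, driftCoef = 0.995, driftSd = 0.05,
                             dropoutProb = 0, artifactProb = 0,
                             invalidProb = 0,
                             interTrial = 33, seed = NULL) {
  stopifnot(nTrials >= 1, sampleRate > 0, heartRate > 0, heartRateSD >= 0,
            all(baselineVelocity > 0), pulseAmplitude >= 0,
            dropoutProb >= 0, dropoutProb <= 1,
            artifactProb >= 0, artifactProb <= 1,
            invalidProb >= 0, invalidProb <= 1)
  if (dropoutProb + artifactProb + invalidProb > 1)
    stop("per-trial event probabilities must sum to at most 1")
  if (interTrial < 31)
    stop("trial spacing too short: epochs (-12..18 s) would overlap")
  list(nTrials = as.integer(nTrials), sampleRate = sampleRate,
       heartRate = heartRate, heartRateSD = heartRateSD,
       baselineVelocity = baselineVelocity,
       pulseAmplitude = pulseAmplitude,
       responseDelta = responseDelta,
       bilateralResponse = bilateralResponse,
       responsePeakTime = responsePeakTime, responseShape = responseShape,
       noiseSd = noiseSd, driftCoef = driftCoef, driftSd = driftSd,
       dropoutProb = dropoutProb, artifactProb = artifactProb,
       invalidProb = invalidProb, interTrial = interTrial, seed = seed)
}

## gamma-shaped activation curve, zero before the cue and beyond 17 s,
## scaled so its mean over the 4-14 s period of interest is exactly 1
.activationCurve <- function(t, peakTime = 7, shape = 3) {
  g0 <- function(x) {
    y <- numeric(length(x))
    pos <- x > 0 & x < 17
    xp <- x[pos] / peakTime
    y[pos] <- pmax(0, xp^shape * exp(shape * (1 - xp)) -
                        (17 / peakTime)^shape * exp(shape * (1 - 17 / peakTime)))
    y
  }
  dense <- seq(4, 14, by = 0.005)
  g0(t) / mean(g0(dense))
}

#' Simulate a full two-channel fTCD session
#'
#' Generates a continuous bilateral velocity trace with cardiac pulsatility
#' (beat-to-beat heart-rate jitter), slow AR(1) drift, white noise, and a
#' per-trial task-evoked response: a bilateral flow increase common to both
#' channels plus a lateralised differential whose normalised mean over the
#' period of interest equals `responseDelta` percentage points in
#' expectation. Prolonged dropouts (runs of zero samples), large-amplitude
#' artifacts and behaviourally invalid trials are injected with the
#' configured per-trial probabilities (mutually exclusive per trial) and
#' recorded in an event log, which downstream tests use as the rejection
#' oracle.
#'
#' @param cfg a [dopplerSimConfig()].
#' @return A [VelocityRecording-class]; `attr(x, "groundTruth")` holds the
#'   true LI, the injected-event log (`data.frame(trial, type)`), the
#'   per-cycle mean velocities of each channel at the cycle midpoints, and
#'   the config.
#' @examples
#' rec <- simulateDopplerSession(dopplerSimConfig(nTrials = 5, seed = 1))
#' @export
simulateDopplerSession <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$sampleRate
  cues <- 20 + (seq_len(cfg$nTrials) - 1) * cfg$interTrial
  dur <- max(cues) + 20
  t <- seq(0, dur, by = 1 / fs)
  n <- length(t)

  ## cardiac cycle schedule with beat-to-beat jitter
  onsets <- numeric(0)
  tt <- 0
  while (tt < dur + 2) {
    onsets <- c(onsets, tt)
    hr <- min(180, max(50, rnorm(1, cfg$heartRate, cfg$heartRateSD)))
    tt <- tt + 60 / hr
  }
  ## pulse waveform: sharp systolic peak, diastolic decay (phase in [0,1))
  cycIdx <- findInterval(t, onsets)
  phase <- (t - onsets[cycIdx]) /
    (c(diff(onsets), diff(onsets)[length(onsets) - 1])[cycIdx])
  pulse <- exp(-((phase - 0.18) / 0.12)^2) + 0.25 * exp(-((phase - 0.45) / 0.2)^2)

  g <- numeric(n)
  for (cue in cues) {
    rel <- t - cue
    w <- rel > 0 & rel < 17
    g[w] <- g[w] + .activationCurve(rel[w], cfg$responsePeakTime,
                                    cfg$responseShape)
  }
  mkDrift <- function() {
    e <- rnorm(n, 0, cfg$driftSd)
    as.numeric(stats::filter(e, cfg$driftCoef, method = "recursive"))
  }
  ## The true LI is defined on the pipeline's normalised scale (percent of
  ## channel mean, baseline-corrected), where a raw modulation u appears as
  ## u / (1 + u * mean(g)) after normalisation. Solve for the raw
  ## coefficient that makes the normalised, baseline-corrected response
  ## coefficient exactly w, so the normalised POI-mean difference equals
  ## responseDelta in expectation.
  f <- mean(g)
  rawCoef <- function(wPct) { w <- wPct / 100; w / (1 - w * f) }
  mkChannel <- function(base, wPct) {
    raw <- base + cfg$pulseAmplitude * pulse + mkDrift() +
      rnorm(n, 0, cfg$noiseSd)
    raw * (1 + rawCoef(wPct) * g)
  }
  left <- mkChannel(cfg$baselineVelocity[["left"]],
                    cfg$bilateralResponse + cfg$responseDelta / 2)
  right <- mkChannel(cfg$baselineVelocity[["right"]],
                     cfg$bilateralResponse - cfg$responseDelta / 2)

  ## ground-truth per-cycle time-weighted means of the clean (pre-injection)
  ## trace
  inRange <- onsets[onsets <= dur]
  nb <- length(inRange)
  cycMid <- cycMeanL <- cycMeanR <- numeric(nb - 1L)
  for (k in seq_len(nb - 1L)) {
    sel <- t >= inRange[k] & t <= inRange[k + 1L]
    if (sum(sel) < 2) { cycMid[k] <- NA; next }
    ts <- t[sel]
    cycMid[k] <- (inRange[k] + inRange[k + 1L]) / 2
    cycMeanL[k] <- pracma::trapz(ts, left[sel]) / (ts[length(ts)] - ts[1])
    cycMeanR[k] <- pracma::trapz(ts, right[sel]) / (ts[length(ts)] - ts[1])
  }

  ## per-trial event injection (mutually exclusive)
  u <- runif(cfg$nTrials)
  type <- rep("none", cfg$nTrials)
  type[u < cfg$dropoutProb] <- "prolonged_dropout"
  type[u >= cfg$dropoutProb &
       u < cfg$dropoutProb + cfg$artifactProb] <- "artifact"
  type[u >= cfg$dropoutProb + cfg$artifactProb &
       u < cfg$dropoutProb + cfg$artifactProb + cfg$invalidProb] <- "behaviour"
  trialValid <- type != "behaviour"
  for (i in seq_len(cfg$nTrials)) {
    if (type[i] == "none" || type[i] == "behaviour") next
    at <- cues[i] + runif(1, 2, 12)
    i0 <- round(at * fs) + 1L
    ch <- sample(c("left", "right"), 1)
    if (type[i] == "prolonged_dropout") {
      idx <- i0:(i0 + sample(1:3, 1))
      if (ch == "left") left[idx] <- 0 else right[idx] <- 0
    } else {
      idx <- i0:(i0 + round(1 * fs))   # 1 s spike survives cycle integration
      if (ch == "left") left[idx] <- left[idx] * 1.65
      else right[idx] <- right[idx] * 1.65
    }
  }

  rec <- VelocityRecording(
    subjectId = "sim", time = t, left = left, right = right,
    markerTime = cues, trialValid = trialValid, sampleRate = fs)
  attr(rec, "groundTruth") <- list(
    trueLI = cfg$responseDelta,
    events = data.frame(trial = which(type != "none"),
                        type = type[type != "none"],
                        stringsAsFactors = FALSE),
    cycleMid = cycMid, cycleMeanLeft = cycMeanL, cycleMeanRight = cycMeanR,
    config = cfg)
  rec
}
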