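## Epoching, artifact rejection, baseline correction, per-trial LIs.

#' Cut a normalised recording into cue-aligned epochs and reject bad trials
#'
#' One epoch is extracted per trial marker, with time zero at the cue to
#' speak. Trials are rejected (with a reason) when the epoch contains a
#' prolonged signal dropout (`"prolonged_dropout"`), any normalised sample
#' outside the artifact bounds (`"artifact"`), or the trial was flagged
#' behaviourally invalid by the examiner (`"behaviour"`, e.g. the child
#' spoke during a silent period or failed to talk). Markers too close to the
#' recording edge for a full epoch are rejected as `"artifact"` with a
#' warning. Accepted epochs are baseline-corrected per channel by
#' subtracting that channel's mean over the baseline window, so each
#' accepted channel's baseline mean is exactly zero.
#'
#' @param rec a normalised [VelocityRecording-class] from
#'   [preprocessRecording()].
#' @param cfg processing configuration ([ftcdConfig()]); uses
#'   `epochWindow`, `baselineWindow` and `artifactBounds`.
#' @return A [TrialEpochSet-class].
#' @export
epochAndReject <- function(rec, cfg = ftcdConfig()) {
  stopifnot(is(rec, "VelocityRecording"))
  if (!rec@normalized)
    stop("recording must be preprocessed first (preprocessRecording)")
  win <- cfg$epochWindow
  base <- cfg$baselineWindow
  bounds <- cfg$artifactBounds
  fs <- rec@sampleRate
  nRel <- floor(win[1] * fs)
  nRelHi <- ceiling(win[2] * fs)
  relIdx <- nRel:nRelHi
  relT <- relIdx / fs
  nT <- length(rec@markerTime)
  nC <- length(relIdx)
  L <- matrix(NA_real_, nT, nC)
  R <- matrix(NA_real_, nT, nC)
  acceptedV <- logical(nT)
  reason <- rep("none", nT)
  baseL <- rep(NA_real_, nT)
  baseR <- rep(NA_real_, nT)
  dropFlag <- if (length(rec@prolongedDropout)) rec@prolongedDropout
              else logical(length(rec@time))
  baseSel <- relT >= base[1] & relT <= base[2]
  if (!any(baseSel)) stop("baseline window contains no samples")
  for (i in seq_len(nT)) {
    m <- round((rec@markerTime[i] - rec@time[1]) * fs) + 1L
    idx <- m + relIdx
    if (idx[1] < 1L || idx[length(idx)] > length(rec@time)) {
      reason[i] <- "artifact"
      warning("trial ", i, " too close to the recording edge; rejected")
      next
    }
    li <- rec@left[idx]; ri <- rec@right[idx]
    L[i, ] <- li; R[i, ] <- ri
    if (length(rec@trialValid) >= i && !rec@trialValid[i]) {
      reason[i] <- "behaviour"
    } else if (any(dropFlag[idx])) {
      reason[i] <- "prolonged_dropout"
    } else if (any(li < bounds[1] | li > bounds[2] |
                   ri < bounds[1] | ri > bounds[2])) {
      reason[i] <- "artifact"
    } else {
      acceptedV[i] <- TRUE
      baseL[i] <- mean(li[baseSel])
      baseR[i] <- mean(ri[baseSel])
      L[i, ] <- li - baseL[i]
      R[i, ] <- ri - baseR[i]
    }
  }
  rd <- S4Vectors::DataFrame(
    trialIndex = seq_len(nT),
    markerTime = rec@markerTime,
    accepted = acceptedV,
    rejectionReason = reason,
    baselineLeft = baseL,
    baselineRight = baseR)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(left = L, right = R, diff = L - R),
    rowData = rd,
    colData = S4Vectors::DataFrame(relTime = relT),
    metadata = list(subjectId = rec@subjectId,
                    epochWindow = win, baselineWindow = base,
                    artifactBounds = bounds, sampleRate = fs))
  new("TrialEpochSet", se)
}

#' Per-trial laterality indices
#'
#' For each accepted epoch, computes the mean-based LI (mean of the
#' left-minus-right difference over the period of interest) and the
#' peak-based LI (mean of the difference over a window of
#' `2 * peakWindowHalfwidth` seconds centred on the sample in the period of
#' interest with the largest absolute difference, truncated at the period's
#' edges; exact ties broken to the earliest sample). Positive values mean
#' left-greater-than-right flow, i.e. left-hemisphere language dominance.
#'
#' @param epochs a [TrialEpochSet-class] from [epochAndReject()].
#' @param poi a [periodOfInterest()].
#' @return The `TrialEpochSet` with `rowData()` columns `liMean` and
#'   `liPeak` (NA for rejected trials).
#' @export
computeTrialLI <- function(epochs, poi = periodOfInterest()) {
  stopifnot(is(epochs, "TrialEpochSet"))
  rt <- relTime(epochs)
  sel <- rt >= poi$start & rt <= poi$end
  if (!any(sel)) stop("malformed configuration: period of interest contains no samples")
  D <- SummarizedExperiment::assay(epochs, "diff")
  rd <- SummarizedExperiment::rowData(epochs)
  liMean <- rep(NA_real_, nrow(D))
  liPeak <- rep(NA_real_, nrow(D))
  poiIdx <- which(sel)
  tPoi <- rt[poiIdx]
  for (i in which(rd$accepted)) {
    d <- D[i, poiIdx]
    liMean[i] <- mean(d)
    star <- which.max(abs(d))       # earliest sample on exact ties
    tStar <- tPoi[star]
    w <- tPoi >= max(poi$start, tStar - poi$peakWindowHalfwidth) &
         tPoi <= min(poi$end, tStar + poi$peakWindowHalfwidth)
    liPeak[i] <- mean(d[w])
  }
  rd$liMean <- liMean
  rd$liPeak <- liPeak
  SummarizedExperiment::rowData(epochs) <- rd
  S4Vectors::metadata(epochs)$poi <- poi
  epochs
}
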