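## Preprocessing of raw fTCD velocity recordings: brief-dropout interpolation,
## prolonged-dropout flagging, heart-cycle integration, normalisation.

#' Default fTCD processing configuration
#'
#' Returns the processing parameters used throughout the pipeline. All
#' windows are in seconds relative to the cue to speak; artifact bounds are
#' in percent of the channel mean (the scale after normalisation).
#'
#' @param epochWindow epoch extent, default `c(-12, 18)` s (covers the 12 s
#'   silent-viewing and 10 s speaking periods with margin).
#' @param baselineWindow baseline-correction window, default `c(-5, 0)` s
#'   (late silent viewing, before the cue to speak).
#' @param artifactBounds accepted range of normalised samples within an
#'   epoch, default `c(60, 140)` percent.
#' @param poiStart,poiEnd period of interest over which laterality indices
#'   are computed, default 4 to 14 s after the cue.
#' @param peakWindowHalfwidth half-width (s) of the window around the peak
#'   difference for the peak-based LI; default 1 (a 2 s window).
#' @param minInterBeat minimum inter-beat interval (s) for heartbeat
#'   detection, default 0.33 (allows up to ~180 bpm, robust for children).
#' @param dropoutThreshold samples at or below this value (cm/s) count as
#'   signal dropout; default 0 (velocity is strictly positive
#'   physiologically).
#' @param minTrials minimum accepted trials for a usable subject LI,
#'   default 12.
#' @param alpha level for per-subject confidence intervals, default 0.05.
#' @param sdLimit sample-level outlier limit in SD units, default 5.
#' @return A named list of processing parameters.
#' @export
ftcdConfig <- function(epochWindow = c(-12, 18),
                       baselineWindow = c(-5, 0),
                       artifactBounds = c(60, 140),
                       poiStart = 4, poiEnd = 14,
                       peakWindowHalfwidth = 1,
                       minInterBeat = 0.33,
                       dropoutThreshold = 0,
                       minTrials = 12,
                       alpha = 0.05,
                       sdLimit = 5) {
  stopifnot(epochWindow[1] < epochWindow[2],
            baselineWindow[1] < baselineWindow[2],
            artifactBounds[1] < artifactBounds[2],
            0 <= poiStart, poiStart < poiEnd,
            peakWindowHalfwidth > 0, minInterBeat > 0)
  list(epochWindow = epochWindow, baselineWindow = baselineWindow,
       artifactBounds = artifactBounds,
       poi = periodOfInterest(poiStart, poiEnd, peakWindowHalfwidth),
       minInterBeat = minInterBeat, dropoutThreshold = dropoutThreshold,
       minTrials = minTrials, alpha = alpha, sdLimit = sdLimit)
}

#' Period of interest for laterality-index computation
#'
#' @param start,end window (s after the cue to speak) over which the
#'   mean-based LI is computed; defaults 4 and 14.
#' @param peakWindowHalfwidth half-width (s) of the peak-LI window; default 1.
#' @return list with elements `start`, `end`, `peakWindowHalfwidth`.
#' @export
periodOfInterest <- function(start = 4, end = 14, peakWindowHalfwidth = 1) {
  stopifnot(0 <= start, start < end, peakWindowHalfwidth > 0)
  list(start = start, end = end, peakWindowHalfwidth = peakWindowHalfwidth)
}

## interpolate isolated dropout samples; flag runs of >= 2
.handleDropouts <- function(v, threshold) {
  bad <- !is.finite(v) | v <= threshold
  prolonged <- logical(length(v))
  if (!any(bad)) return(list(v = v, prolonged = prolonged))
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (r$lengths[k] == 1L && i0 > 1L && i1 < length(v)) {
      v[i0] <- (v[i0 - 1L] + v[i1 + 1L]) / 2
    } else {
      prolonged[i0:i1] <- TRUE
      ## keep the trace finite for downstream arithmetic; the trial is
      ## rejected regardless of the filled values
      left <- if (i0 > 1L) v[i0 - 1L] else NA_real_
      right <- if (i1 < length(v)) v[i1 + 1L] else NA_real_
      fill <- mean(c(left, right), na.rm = TRUE)
      if (!is.finite(fill)) fill <- mean(v[!bad])
      v[i0:i1] <- fill
    }
  }
  list(v = v, prolonged = prolonged)
}

## detect heartbeat peaks on a summed channel; returns fractional sample
## positions (parabolic sub-sample refinement of each discrete peak, so a
## cycle spans one full period regardless of the sampling phase)
.detectBeats <- function(s, fs, minInterBeat) {
  if (sd(s) < 1e-10 * (abs(mean(s)) + 1e-12) || sd(s) == 0)
    stop("unusable recording: no detectable heartbeats (flat signal)")
  minDist <- max(1L, ceiling(minInterBeat * fs))
  pk <- pracma::findpeaks(s, minpeakdistance = minDist,
                          minpeakheight = mean(s))
  if (is.null(pk) || nrow(pk) < 3L)
    stop("unusable recording: no detectable heartbeats")
  idx <- sort(pk[, 2])
  idx <- idx[idx > 1L & idx < length(s)]
  denom <- s[idx - 1L] - 2 * s[idx] + s[idx + 1L]
  delta <- ifelse(abs(denom) > 1e-12,
                  0.5 * (s[idx - 1L] - s[idx + 1L]) / denom, 0)
  idx + pmax(-0.5, pmin(0.5, delta))
}

## heart-cycle integration of one channel: time-weighted (trapezoidal) mean
## of each beat-to-beat cycle between fractional beat positions, assigned to
## the cycle midpoint and resampled onto the original grid. Cubic resampling
## keeps slow evoked-response curvature intact (linear interpolation biases
## the period-of-interest mean of a curved response).
.cycleIntegrate <- function(t, v, beats) {
  dt <- t[2L] - t[1L]
  bt <- t[1L] + (beats - 1) * dt              # fractional beat times
  bv <- approx(t, v, xout = bt)$y
  nb <- length(beats)
  mids <- numeric(nb - 1L)
  means <- numeric(nb - 1L)
  for (k in seq_len(nb - 1L)) {
    i0 <- ceiling(beats[k]); i1 <- floor(beats[k + 1L])
    tt <- c(bt[k], t[i0:i1], bt[k + 1L])
    vv <- c(bv[k], v[i0:i1], bv[k + 1L])
    keep <- !duplicated(tt)
    means[k] <- pracma::trapz(tt[keep], vv[keep]) / (bt[k + 1L] - bt[k])
    mids[k] <- (bt[k] + bt[k + 1L]) / 2
  }
  out <- stats::spline(mids, means, xout = t, method = "natural")$y
  out[t < mids[1L]] <- means[1L]
  out[t > mids[length(mids)]] <- means[length(means)]
  list(v = out, cycleMid = mids, cycleMean = means)
}

#' Preprocess a raw fTCD recording
#'
#' Applies, in order: interpolation of isolated signal dropouts (a single
#' sample at or below the dropout threshold is replaced by the mean of its
#' flanking samples), flagging of prolonged dropout runs (two or more
#' samples; the containing trial is later rejected), heart-cycle integration
#' (heartbeats detected as peaks of the summed left+right channel with a
#' minimum inter-beat interval; each cardiac cycle is replaced by its
#' time-weighted mean, then resampled to the original grid), and
#' normalisation of each channel so its recording-wide mean equals 100
#' (percent units). Heart-cycle integration preserves the overall channel
#' mean to within 0.5 percent.
#'
#' @param rec a raw [VelocityRecording-class].
#' @param cfg processing configuration from [ftcdConfig()].
#' @return The cleaned, normalised [VelocityRecording-class] with
#'   `@normalized = TRUE`, per-sample prolonged-dropout flags, and cycle
#'   means stored in `@meta`.
#' @export
preprocessRecording <- function(rec, cfg = ftcdConfig()) {
  stopifnot(is(rec, "VelocityRecording"))
  if (rec@normalized) stop("recording is already normalized")
  dl <- .handleDropouts(rec@left, cfg$dropoutThreshold)
  dr <- .handleDropouts(rec@right, cfg$dropoutThreshold)
  prolonged <- dl$prolonged | dr$prolonged
  beats <- .detectBeats(dl$v + dr$v, rec@sampleRate, cfg$minInterBeat)
  cl <- .cycleIntegrate(rec@time, dl$v, beats)
  cr <- .cycleIntegrate(rec@time, dr$v, beats)
  left <- 100 * cl$v / mean(cl$v)
  right <- 100 * cr$v / mean(cr$v)
  initialize(rec, left = left, right = right, normalized = TRUE,
             prolongedDropout = prolonged,
             meta = c(rec@meta, list(
               beats = beats,
               cycleMid = cl$cycleMid,
               cycleMeanLeft = cl$cycleMean,
               cycleMeanRight = cr$cycleMean,
               channelMeanLeft = mean(cl$v),
               channelMeanRight = mean(cr$v),
               config = cfg)))
}
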