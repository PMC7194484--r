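## Per-subject laterality summaries, sample-level exclusions, reliability.

## core summary from per-trial quantities; used both by summarizeSubject()
## (full pipeline) and by simulation helpers that work at the trial-LI level.
.summarizeTrialLIs <- function(subjectId, liMean, liPeak,
                               meanLeftFlow = NA_real_,
                               meanRightFlow = NA_real_,
                               minTrials = 12, alpha = 0.05) {
  n <- length(liMean)
  tcrit <- if (n >= 2) qt(1 - alpha / 2, n - 1) else NA_real_
  mkCI <- function(x) {
    if (n < 2) return(c(mean = if (n) mean(x) else NA_real_,
                        se = NA_real_, lo = NA_real_, hi = NA_real_))
    m <- mean(x); s <- sd(x) / sqrt(n)
    c(mean = m, se = s, lo = m - tcrit * s, hi = m + tcrit * s)
  }
  cm <- mkCI(liMean)
  cp <- mkCI(liPeak)
  category <- NA_character_
  binaryTypical <- NA_character_
  if (n >= 2) {
    category <- if (cm["lo"] > 0) "left" else if (cm["hi"] < 0) "right"
                else "bilateral"
    ## typical = significantly left-lateralised on the peak-based LI;
    ## atypical = peak CI spans, or falls below, zero
    binaryTypical <- if (cp["lo"] > 0) "typical" else "atypical"
  }
  odd <- if (n >= 1) seq(1, n, by = 2) else integer(0)
  even <- if (n >= 2) seq(2, n, by = 2) else integer(0)
  excluded <- n < minTrials || n < 2
  data.frame(
    subjectId = as.character(subjectId), nAccepted = n,
    liMean = unname(cm["mean"]), liPeak = unname(cp["mean"]),
    se = unname(cm["se"]), sePeak = unname(cp["se"]),
    ciLow = unname(cm["lo"]), ciHigh = unname(cm["hi"]),
    ciLowPeak = unname(cp["lo"]), ciHighPeak = unname(cp["hi"]),
    category = category, binaryTypical = binaryTypical,
    liOdd = if (length(odd)) mean(liMean[odd]) else NA_real_,
    liEven = if (length(even)) mean(liMean[even]) else NA_real_,
    meanLeftFlow = meanLeftFlow, meanRightFlow = meanRightFlow,
    excluded = excluded,
    exclusionReason = if (excluded) "too_few_trials" else "none",
    stringsAsFactors = FALSE)
}

#' Summarize a subject's accepted trials into a laterality phenotype
#'
#' The subject's mean-based (and peak-based) LI is the mean of the accepted
#' per-trial LIs; its standard error is the sample SD of the trial LIs
#' divided by the square root of the number of accepted trials, and the
#' confidence interval uses the Student-t quantile with n-1 degrees of
#' freedom. The laterality category is `"left"` when the CI lies entirely
#' above zero, `"right"` when entirely below, `"bilateral"` when it spans
#' zero. The binary typical/atypical code is based on the peak-based LI:
#' `"typical"` only when its CI lies entirely above zero. Odd- and
#' even-half LIs are means over the accepted trials in presentation order
#' (1st, 3rd, ... vs 2nd, 4th, ...). Mean left and right flow are the mean
#' normalised channel values over the period of interest across accepted
#' trials (baseline level added back). Subjects with fewer than `minTrials`
#' accepted trials are marked excluded with reason `"too_few_trials"`.
#'
#' @param epochs a [TrialEpochSet-class]; per-trial LIs are computed with
#'   [computeTrialLI()] if not already present.
#' @param poi [periodOfInterest()].
#' @param minTrials minimum accepted trials, default 12.
#' @param alpha CI level complement, default 0.05.
#' @return A one-subject [SubjectLaterality-class].
#' @export
summarizeSubject <- function(epochs, poi = periodOfInterest(),
                             minTrials = 12, alpha = 0.05) {
  stopifnot(is(epochs, "TrialEpochSet"))
  rd <- SummarizedExperiment::rowData(epochs)
  if (!"liMean" %in% colnames(rd)) {
    epochs <- computeTrialLI(epochs, poi)
    rd <- SummarizedExperiment::rowData(epochs)
  }
  acc <- which(rd$accepted)
  rt <- relTime(epochs)
  sel <- rt >= poi$start & rt <= poi$end
  if (length(acc)) {
    Lp <- SummarizedExperiment::assay(epochs, "left")[acc, sel, drop = FALSE]
    Rp <- SummarizedExperiment::assay(epochs, "right")[acc, sel, drop = FALSE]
    mlf <- mean(rowMeans(Lp) + rd$baselineLeft[acc])
    mrf <- mean(rowMeans(Rp) + rd$baselineRight[acc])
  } else {
    mlf <- mrf <- NA_real_
  }
  d <- .summarizeTrialLIs(
    S4Vectors::metadata(epochs)$subjectId %||% "subject",
    rd$liMean[acc], rd$liPeak[acc],
    meanLeftFlow = mlf, meanRightFlow = mrf,
    minTrials = minTrials, alpha = alpha)
  new("SubjectLaterality", data = d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a SubjectLaterality table from per-trial LIs
#'
#' Lower-level constructor used when per-trial laterality indices are
#' available without the raw recordings (e.g. a deposited per-trial LI table
#' or trial-level simulations): applies the same subject-level summary rules
#' as [summarizeSubject()].
#'
#' @param trialLIs data.frame with columns `subjectId`, `trialLIMean` and
#'   optionally `trialLIPeak` (defaults to the mean-based values).
#' @param minTrials,alpha as in [summarizeSubject()].
#' @return A [SubjectLaterality-class] with one row per subject.
#' @export
subjectsFromTrialLIs <- function(trialLIs, minTrials = 12, alpha = 0.05) {
  stopifnot(all(c("subjectId", "trialLIMean") %in% colnames(trialLIs)))
  if (!"trialLIPeak" %in% colnames(trialLIs))
    trialLIs$trialLIPeak <- trialLIs$trialLIMean
  parts <- lapply(split(trialLIs, trialLIs$subjectId), function(d)
    .summarizeTrialLIs(d$subjectId[1], d$trialLIMean, d$trialLIPeak,
                       minTrials = minTrials, alpha = alpha))
  d <- do.call(rbind, parts)
  rownames(d) <- NULL
  ## keep input order of first appearance
  d <- d[match(unique(trialLIs$subjectId), d$subjectId), , drop = FALSE]
  rownames(d) <- NULL
  new("SubjectLaterality", data = d)
}

#' Flag sample-level outliers on the mean-based LI
#'
#' Single pass: the mean and SD of `liMean` are computed over currently
#' non-excluded subjects, and any subject more than `sdLimit` SDs from that
#' mean is marked excluded with reason `"outlier_5sd"`. Pair-level
#' propagation (dropping the cotwin) is applied by the twin-table builder,
#' not here.
#'
#' @param subjects a [SubjectLaterality-class].
#' @param sdLimit SD multiple beyond which a subject is excluded; default 5.
#' @return The updated [SubjectLaterality-class].
#' @export
applySampleExclusions <- function(subjects, sdLimit = 5) {
  stopifnot(is(subjects, "SubjectLaterality"))
  d <- subjects@data
  keep <- !d$excluded & is.finite(d$liMean)
  if (sum(keep) < 3) stop("need at least 3 non-excluded subjects")
  m <- mean(d$liMean[keep])
  s <- sd(d$liMean[keep])
  out <- keep & abs(d$liMean - m) > sdLimit * s
  d$excluded[out] <- TRUE
  d$exclusionReason[out] <- "outlier_5sd"
  initialize(subjects, data = d)
}

#' Split-half reliability of the laterality index
#'
#' Pearson correlation between the odd-trial and even-trial half-sample LIs
#' across non-excluded subjects, plus the Spearman-Brown corrected
#' full-length reliability `2r / (1 + r)` (reported separately, never
#' substituted for the raw half-half correlation).
#'
#' @param subjects a [SubjectLaterality-class].
#' @return list with `r` (half-half Pearson correlation), `spearmanBrown`,
#'   and `n` (subjects used).
#' @export
splitHalfReliability <- function(subjects) {
  stopifnot(is(subjects, "SubjectLaterality"))
  d <- subjects@data
  keep <- !d$excluded & is.finite(d$liOdd) & is.finite(d$liEven)
  if (sum(keep) < 3) stop("need at least 3 subjects with both half LIs")
  x <- d$liOdd[keep]; y <- d$liEven[keep]
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in a half-sample LI; reliability undefined")
  r <- cor(x, y)
  list(r = r, spearmanBrown = 2 * r / (1 + r), n = sum(keep))
}
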