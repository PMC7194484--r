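#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats approx coef cor cor.test dnorm mad median na.omit optim
#'   optimize optimHess pchisq pnorm pt qbeta qchisq qnorm qt quantile rnorm
#'   runif sd setNames t.test uniroot var
#' @importFrom utils read.csv write.csv head tail
NULL

## ---------------------------------------------------------------------------
## Raw fTCD recording
## ---------------------------------------------------------------------------

#' VelocityRecording: a bilateral fTCD blood-flow-velocity recording
#'
#' Container for one subject's raw (or preprocessed) functional transcranial
#' Doppler session: left and right middle-cerebral-artery velocity channels on
#' a common uniform time grid, plus the marker channel giving the onset time
#' of each cue to speak, and an optional per-trial behavioural validity flag.
#'
#' @slot subjectId character(1) subject identifier.
#' @slot sampleRate numeric(1), samples per second.
#' @slot time numeric, seconds; strictly increasing uniform grid.
#' @slot left,right numeric, velocity in cm/s (raw) or percent of channel
#'   mean (after [preprocessRecording()]).
#' @slot markerTime numeric, onset time (s) of each cue to speak; strictly
#'   increasing, within the time range.
#' @slot trialValid logical, one per marker; behavioural validity from the
#'   examiner's notes (`TRUE` = usable).
#' @slot normalized logical(1), `TRUE` once heart-cycle integration and
#'   normalisation to a channel mean of 100 have been applied.
#' @slot prolongedDropout logical, one per sample; marks samples belonging to
#'   a dropout run of two or more samples (the containing trial is later
#'   rejected).
#' @slot meta list of processing provenance (cycle midpoints, configuration).
#'
#' @seealso [readVelocityRecording()], [preprocessRecording()],
#'   [simulateDopplerSession()]
#' @export
setClass("VelocityRecording",
  representation(
    subjectId = "character",
    sampleRate = "numeric",
    time = "numeric",
    left = "numeric",
    right = "numeric",
    markerTime = "numeric",
    trialValid = "logical",
    normalized = "logical",
    prolongedDropout = "logical",
    meta = "list"
  ),
  prototype(normalized = FALSE, meta = list())
)

setValidity("VelocityRecording", function(object) {
  msg <- character()
  n <- length(object@time)
  if (n < 2L) msg <- c(msg, "recording needs at least 2 samples")
  if (length(object@left) != n || length(object@right) != n)
    msg <- c(msg, "time, left and right must have equal length")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (n >= 2L) {
    dt <- diff(object@time)
    if (any(dt <= 0)) msg <- c(msg, "time must be strictly increasing")
    else if (max(dt) - min(dt) > 1e-6 * mean(dt) + 1e-9)
      msg <- c(msg, "time must be a uniform grid")
  }
  nm <- length(object@markerTime)
  if (nm > 1L && any(diff(object@markerTime) <= 0))
    msg <- c(msg, "markers must be strictly increasing")
  if (nm > 0L && (min(object@markerTime) < object@time[1L] ||
                  max(object@markerTime) > object@time[n]))
    msg <- c(msg, "markers must lie within the time range")
  if (length(object@trialValid) != nm)
    msg <- c(msg, "trialValid must have one entry per marker")
  if (length(object@prolongedDropout) &&
      length(object@prolongedDropout) != n)
    msg <- c(msg, "prolongedDropout must have one entry per sample")
  if (length(msg)) msg else TRUE
})

#' Construct a VelocityRecording
#'
#' @param subjectId subject identifier.
#' @param time numeric vector of sample times in seconds (uniform grid).
#' @param left,right numeric velocity channels (cm/s).
#' @param markerTime onset times (s) of the cue to speak, one per trial.
#' @param trialValid optional logical per marker; defaults to all `TRUE`.
#' @param sampleRate samples/second; inferred from `time` when missing and
#'   cross-checked against it otherwise.
#' @return A [VelocityRecording-class] object.
#' @export
VelocityRecording <- function(subjectId, time, left, right, markerTime,
                              trialValid = NULL, sampleRate = NULL) {
  dt <- median(diff(time))
  fs <- 1 / dt
  if (!is.null(sampleRate)) {
    if (abs(sampleRate - fs) > 0.01 * fs)
      stop("declared sampleRate (", sampleRate,
           ") disagrees with the time grid (", signif(fs, 6), " Hz)")
    fs <- sampleRate
  }
  if (is.null(trialValid)) trialValid <- rep(TRUE, length(markerTime))
  new("VelocityRecording",
      subjectId = as.character(subjectId), sampleRate = fs,
      time = as.numeric(time), left = as.numeric(left),
      right = as.numeric(right), markerTime = as.numeric(markerTime),
      trialValid = as.logical(trialValid),
      normalized = FALSE, prolongedDropout = logical(0), meta = list())
}

## ---------------------------------------------------------------------------
## Epochs
## ---------------------------------------------------------------------------

#' TrialEpochSet: cue-aligned two-channel epochs for one subject
#'
#' Extends [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' with trials as rows and epoch time points as columns. Assays `"left"`,
#' `"right"` and `"diff"` hold the normalised (and, for accepted trials,
#' baseline-corrected) channel values in percent of the channel mean;
#' `rowData()` carries per-trial acceptance status, rejection reason and the
#' mean- and peak-based per-trial laterality indices; `colData()$relTime` is
#' the time of each column relative to the cue to speak (s).
#'
#' @seealso [epochAndReject()], [computeTrialLI()], [summarizeSubject()]
#' @export
setClass("TrialEpochSet", contains = "SummarizedExperiment")

setValidity("TrialEpochSet", function(object) {
  msg <- character()
  need <- c("left", "right", "diff")
  if (!all(need %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays must include 'left', 'right' and 'diff'")
  rd <- SummarizedExperiment::rowData(object)
  for (col in c("trialIndex", "accepted", "rejectionReason"))
    if (!col %in% colnames(rd)) msg <- c(msg, paste0("rowData needs ", col))
  if (!"relTime" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData needs relTime")
  if ("accepted" %in% colnames(rd) && "rejectionReason" %in% colnames(rd)) {
    if (any(rd$accepted & rd$rejectionReason != "none"))
      msg <- c(msg, "accepted trials must have rejectionReason 'none'")
  }
  if (length(msg)) msg else TRUE
})

.rejection_levels <- c("none", "prolonged_dropout", "artifact", "behaviour")

## ---------------------------------------------------------------------------
## Subject summaries
## ---------------------------------------------------------------------------

.subject_cols <- c("subjectId", "nAccepted", "liMean", "liPeak",
                   "se", "sePeak", "ciLow", "ciHigh",
                   "ciLowPeak", "ciHighPeak",
                   "category", "binaryTypical", "liOdd", "liEven",
                   "meanLeftFlow", "meanRightFlow",
                   "excluded", "exclusionReason")

#' SubjectLaterality: per-subject laterality summaries
#'
#' A vector-like S4 table, one row per subject, holding the mean-based and
#' peak-based laterality indices with their standard errors and 95 percent
#' confidence intervals, the left/bilateral/right category, the
#' typical/atypical binary code, odd- and even-trial half-sample indices,
#' mean normalised left and right flow over the period of interest, and
#' exclusion status.
#'
#' @slot data data.frame with one row per subject (columns documented in
#'   [summarizeSubject()]).
#' @seealso [summarizeSubject()], [applySampleExclusions()],
#'   [splitHalfReliability()]
#' @export
setClass("SubjectLaterality", representation(data = "data.frame"))

setValidity("SubjectLaterality", function(object) {
  msg <- character()
  missing_cols <- setdiff(.subject_cols, colnames(object@data))
  if (length(missing_cols))
    msg <- c(msg, paste("missing columns:", paste(missing_cols, collapse = ", ")))
  d <- object@data
  if (!length(msg) && nrow(d)) {
    ok <- !d$excluded & is.finite(d$se) & d$se >= 0
    if (any(ok & !(d$ciLow <= d$liMean & d$liMean <= d$ciHigh), na.rm = TRUE))
      msg <- c(msg, "liMean must lie within its confidence interval")
    if (any(ok & d$category == "left" & d$ciLow <= 0, na.rm = TRUE))
      msg <- c(msg, "category 'left' requires ciLow > 0")
    if (any(ok & d$category == "right" & d$ciHigh >= 0, na.rm = TRUE))
      msg <- c(msg, "category 'right' requires ciHigh < 0")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Twin pair table
## ---------------------------------------------------------------------------

#' TwinPairTable: double-entry-ready twin phenotype table
#'
#' One row per twin pair. Phenotype values are stored in paired columns named
#' `<phenotype>_1` and `<phenotype>_2` (twin order is arbitrary; all
#' likelihoods are symmetric under within-pair exchange). The table is the
#' single-entry master; double-entry views are derived by
#' [doubleEntry()] where a symmetric statistic needs them.
#'
#' @slot pairs data.frame with columns `familyId`, `zygosity` ("MZ"/"DZ"),
#'   `sexPair` ("FF"/"MM"/"MF"/NA), and `<pheno>_1`/`<pheno>_2` per phenotype.
#' @slot phenotypes character vector of phenotype names present.
#' @seealso [TwinPairTable()], [simulateTwinPhenotypes()], [fitUnivariate()]
#' @export
setClass("TwinPairTable",
  representation(pairs = "data.frame", phenotypes = "character"))

setValidity("TwinPairTable", function(object) {
  msg <- character()
  p <- object@pairs
  for (col in c("familyId", "zygosity"))
    if (!col %in% colnames(p)) msg <- c(msg, paste("missing column", col))
  if ("zygosity" %in% colnames(p) &&
      !all(p$zygosity %in% c("MZ", "DZ")))
    msg <- c(msg, "zygosity must be 'MZ' or 'DZ' for every pair")
  for (ph in object@phenotypes) {
    if (!all(paste0(ph, c("_1", "_2")) %in% colnames(p)))
      msg <- c(msg, paste0("phenotype '", ph, "' needs columns ",
                           ph, "_1 and ", ph, "_2"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TwinPairTable
#'
#' @param pairs data.frame with columns `familyId`, `zygosity` and paired
#'   phenotype columns `<pheno>_1`, `<pheno>_2`; an optional `sexPair` column
#'   is kept and otherwise filled with `NA`.
#' @param phenotypes phenotype names; inferred from `_1`/`_2` column pairs
#'   when missing.
#' @return A [TwinPairTable-class].
#' @export
TwinPairTable <- function(pairs, phenotypes = NULL) {
  pairs <- as.data.frame(pairs)
  if (is.null(phenotypes)) {
    c1 <- sub("_1$", "", grep("_1$", colnames(pairs), value = TRUE))
    c2 <- sub("_2$", "", grep("_2$", colnames(pairs), value = TRUE))
    phenotypes <- intersect(c1, c2)
  }
  if (!"sexPair" %in% colnames(pairs)) pairs$sexPair <- NA_character_
  pairs$zygosity <- as.character(pairs$zygosity)
  new("TwinPairTable", pairs = pairs, phenotypes = phenotypes)
}

## ---------------------------------------------------------------------------
## Model fits and results
## ---------------------------------------------------------------------------

#' VarianceFit: maximum-likelihood twin variance decomposition
#'
#' Result of [fitUnivariate()]: standardized variance proportions a2
#' (additive genetic), c2 (shared environment) and e2 (nonshared
#' environment), which sum to one; the phenotypic mean and total variance;
#' the maximised log-likelihood; and the data the model was fitted to (kept
#' so that profile intervals and nested-model comparisons can refit).
#'
#' @slot model "ACE", "AE", "CE" or "E".
#' @slot a2,c2,e2 numeric(1) variance proportions; components absent from the
#'   model are exactly 0.
#' @slot mean,totalVariance numeric(1) phenotypic mean and total variance.
#' @slot loglik numeric(1) maximised log-likelihood.
#' @slot npar numeric(1) number of free parameters.
#' @slot nMZ,nDZ numeric(1) complete-pair counts entering the likelihood.
#' @slot ciA2 numeric(2) profile-likelihood interval for a2 (NA until
#'   [profileCI()] is called).
#' @slot convergence numeric(1) optimiser convergence code (0 = converged).
#' @slot mzData,dzData two-column matrices of pair values (twin1, twin2).
#' @slot phenotype character(1) phenotype name.
#' @export
setClass("VarianceFit",
  representation(
    model = "character", a2 = "numeric", c2 = "numeric", e2 = "numeric",
    mean = "numeric", totalVariance = "numeric", loglik = "numeric",
    npar = "numeric", nMZ = "numeric", nDZ = "numeric",
    ciA2 = "numeric", convergence = "numeric",
    mzData = "matrix", dzData = "matrix", phenotype = "character"
  ),
  prototype(ciA2 = c(NA_real_, NA_real_), phenotype = "value")
)

setValidity("VarianceFit", function(object) {
  msg <- character()
  if (!object@model %in% c("ACE", "AE", "CE", "E"))
    msg <- c(msg, "model must be ACE, AE, CE or E")
  s <- object@a2 + object@c2 + object@e2
  if (abs(s - 1) > 1e-8)
    msg <- c(msg, "a2 + c2 + e2 must equal 1")
  if (!grepl("A", object@model) && object@a2 != 0)
    msg <- c(msg, "a2 must be exactly 0 when absent from the model")
  if (!grepl("C", object@model) && object@c2 != 0)
    msg <- c(msg, "c2 must be exactly 0 when absent from the model")
  if (length(msg)) msg else TRUE
})

#' CholeskyFit: trivariate AE Cholesky decomposition
#'
#' Result of [fitCholeskyTrivariate()]: unsquared standardized lower-triangular
#' path matrices for the additive-genetic (A) and nonshared-environment (E)
#' factors over three traits, with standard errors from the observed
#' information matrix.
#'
#' @slot traits character(3) trait names in model order.
#' @slot pathsA,pathsE 3x3 lower-triangular standardized path matrices.
#' @slot seA,seE 3x3 matrices of standard errors for the paths.
#' @slot loglik numeric(1) maximised log-likelihood.
#' @slot nMZ,nDZ numeric(1) pair counts.
#' @slot convergence numeric(1) optimiser code.
#' @export
setClass("CholeskyFit",
  representation(
    traits = "character", pathsA = "matrix", pathsE = "matrix",
    seA = "matrix", seE = "matrix", loglik = "numeric",
    nMZ = "numeric", nDZ = "numeric", convergence = "numeric"
  ))

setValidity("CholeskyFit", function(object) {
  tot <- rowSums(object@pathsA^2) + rowSums(object@pathsE^2)
  if (any(abs(tot - 1) > 1e-6))
    return("standardized A and E paths must satisfy sum of squares = 1 per trait")
  TRUE
})

#' PowerResult: power to detect heritability in an AE twin design
#'
#' @slot nMZ,nDZ numeric(1) pair counts.
#' @slot a2True numeric(1) generating heritability.
#' @slot alpha numeric(1) test level.
#' @slot power numeric(1) probability of rejecting a2 = 0.
#' @slot method "ncp" (noncentral chi-square approximation) or "simulation".
#' @slot nReps numeric(1) replicates (simulation only; NA for ncp).
#' @slot lambda numeric(1) noncentrality parameter (ncp only; NA otherwise).
#' @slot mixture logical(1) whether the 50:50 boundary mixture reference was
#'   used in place of the standard chi-square(1).
#' @export
setClass("PowerResult",
  representation(nMZ = "numeric", nDZ = "numeric", a2True = "numeric",
                 alpha = "numeric", power = "numeric", method = "character",
                 nReps = "numeric", lambda = "numeric", mixture = "logical"))

setValidity("PowerResult", function(object) {
  msg <- character()
  if (object@power < object@alpha * 0.5 - 1e-8 || object@power > 1 + 1e-12)
    msg <- c(msg, "power must lie in [alpha/2, 1]")
  if (!object@method %in% c("ncp", "simulation"))
    msg <- c(msg, "method must be 'ncp' or 'simulation'")
  if (length(msg)) msg else TRUE
})

#' ExtremesResult: DeFries-Fulker style extremes comparison
#'
#' Probands are twins scoring past a cutoff; their cotwins' scores are
#' compared between MZ and DZ pairs by a Welch two-sample t-test. Under a
#' genetic aetiology of the extreme, MZ cotwins regress less toward the
#' population mean than DZ cotwins.
#'
#' @slot phenotype character(1).
#' @slot cutoff,direction selection rule applied to proband scores.
#' @slot nProbandsMZ,nProbandsDZ proband counts (double entry unless
#'   `singleEntry`).
#' @slot probandMeanMZ,probandMeanDZ,cotwinMeanMZ,cotwinMeanDZ group means.
#' @slot probandSdMZ,probandSdDZ,cotwinSdMZ,cotwinSdDZ group SDs.
#' @slot t,df,p Welch statistic, Satterthwaite df, two-sided p-value.
#' @slot singleEntry logical(1) whether the single-entry variant was used.
#' @export
setClass("ExtremesResult",
  representation(phenotype = "character", cutoff = "numeric",
                 direction = "character",
                 nProbandsMZ = "numeric", nProbandsDZ = "numeric",
                 probandMeanMZ = "numeric", probandMeanDZ = "numeric",
                 cotwinMeanMZ = "numeric", cotwinMeanDZ = "numeric",
                 probandSdMZ = "numeric", probandSdDZ = "numeric",
                 cotwinSdMZ = "numeric", cotwinSdDZ = "numeric",
                 t = "numeric", df = "numeric", p = "numeric",
                 singleEntry = "logical"))

setValidity("ExtremesResult", function(object) {
  msg <- character()
  if (object@nProbandsMZ < 2 || object@nProbandsDZ < 2)
    msg <- c(msg, "need at least 2 probands per zygosity group")
  if (!is.na(object@df) && object@df <= 0)
    msg <- c(msg, "df must be positive")
  if (length(msg)) msg else TRUE
})
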