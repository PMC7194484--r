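## Accessors, show methods and coercions for the S4 classes.

#' @rdname VelocityRecording-class
#' @export
setMethod("subjectId", "VelocityRecording", function(x) x@subjectId)

#' @rdname VelocityRecording-class
#' @export
setMethod("sampleRate", "VelocityRecording", function(x) x@sampleRate)

#' @rdname VelocityRecording-class
#' @export
setMethod("markerTimes", "VelocityRecording", function(x) x@markerTime)

#' @rdname VelocityRecording-class
#' @export
setMethod("length", "VelocityRecording", function(x) length(x@time))

setMethod("show", "VelocityRecording", function(object) {
  cat("VelocityRecording '", object@subjectId, "'\n", sep = "")
  cat("  ", length(object@time), " samples at ", signif(object@sampleRate, 5),
      " Hz (", signif(diff(range(object@time)), 5), " s)\n", sep = "")
  cat("  ", length(object@markerTime), " trial markers; normalized: ",
      object@normalized, "\n", sep = "")
  if (any(object@prolongedDropout))
    cat("  ", sum(object@prolongedDropout),
        " samples flagged as prolonged dropout\n", sep = "")
})

#' @rdname TrialEpochSet-class
#' @export
setMethod("accepted", "TrialEpochSet", function(x)
  SummarizedExperiment::rowData(x)$accepted)

#' @rdname TrialEpochSet-class
#' @export
setMethod("rejectionReason", "TrialEpochSet", function(x)
  SummarizedExperiment::rowData(x)$rejectionReason)

#' @rdname TrialEpochSet-class
#' @export
setMethod("relTime", "TrialEpochSet", function(x)
  SummarizedExperiment::colData(x)$relTime)

#' @rdname TrialEpochSet-class
#' @param ... for `trialLI`, `method = c("mean", "peak")`.
#' @param method which per-trial laterality index to return.
#' @export
setMethod("trialLI", "TrialEpochSet", function(x, method = c("mean", "peak")) {
  method <- match.arg(method)
  rd <- SummarizedExperiment::rowData(x)
  col <- if (method == "mean") "liMean" else "liPeak"
  if (!col %in% colnames(rd))
    stop("per-trial LIs not yet computed; run computeTrialLI() first")
  rd[[col]]
})

setMethod("show", "TrialEpochSet", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("TrialEpochSet: ", nrow(object), " trials x ", ncol(object),
      " time points\n", sep = "")
  rt <- relTime(object)
  cat("  relTime: [", min(rt), ", ", max(rt), "] s\n", sep = "")
  cat("  accepted: ", sum(rd$accepted), "/", nrow(object), sep = "")
  if (any(!rd$accepted)) {
    tab <- table(factor(rd$rejectionReason[!rd$accepted],
                        levels = .rejection_levels))
    tab <- tab[tab > 0]
    cat("  (", paste(names(tab), tab, sep = ": ", collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  if ("liMean" %in% colnames(rd))
    cat("  per-trial LIs computed (mean, peak)\n")
})

#' @rdname SubjectLaterality-class
#' @param x,object a SubjectLaterality.
#' @param ... unused.
#' @export
setMethod("length", "SubjectLaterality", function(x) nrow(x@data))

#' @rdname SubjectLaterality-class
#' @param row.names,optional passed on to data.frame methods.
#' @export
setMethod("as.data.frame", "SubjectLaterality",
  function(x, row.names = NULL, optional = FALSE, ...) x@data)

#' @rdname SubjectLaterality-class
#' @param i subject index or logical selector.
#' @export
setMethod("[", "SubjectLaterality", function(x, i, ...) {
  initialize(x, data = x@data[i, , drop = FALSE])
})

#' Combine subject summaries
#' @rdname SubjectLaterality-class
#' @export
setMethod("c", "SubjectLaterality", function(x, ...) {
  rest <- list(...)
  dfs <- c(list(x@data), lapply(rest, function(s) s@data))
  initialize(x, data = do.call(rbind, dfs))
})

setMethod("show", "SubjectLaterality", function(object) {
  d <- object@data
  cat("SubjectLaterality: ", nrow(d), " subject(s)\n", sep = "")
  if (nrow(d)) {
    keep <- !d$excluded
    cat("  excluded: ", sum(d$excluded), "\n", sep = "")
    if (any(keep)) {
      cat("  liMean: median ", signif(median(d$liMean[keep]), 3),
          ", categories: ", sep = "")
      tab <- table(factor(d$category[keep],
                          levels = c("left", "bilateral", "right")))
      cat(paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    }
  }
})

#' @rdname TwinPairTable-class
#' @export
setMethod("pairData", "TwinPairTable", function(x) x@pairs)

#' @rdname TwinPairTable-class
#' @export
setMethod("phenotypes", "TwinPairTable", function(x) x@phenotypes)

#' @rdname TwinPairTable-class
#' @export
setMethod("length", "TwinPairTable", function(x) nrow(x@pairs))

#' Double-entry view of one phenotype
#'
#' Returns a data.frame in which every complete pair appears twice, once per
#' twin ordering, with columns `familyId`, `zygosity`, `self` and `cotwin`.
#' Symmetric statistics (double-entry correlations, extremes selection)
#' operate on this view.
#' @rdname TwinPairTable-class
#' @export
setMethod("doubleEntry", "TwinPairTable", function(x, phenotype) {
  v <- .pairValues(x, phenotype)
  base <- data.frame(familyId = v$familyId, zygosity = v$zygosity)
  rbind(cbind(base, self = v$v1, cotwin = v$v2),
        cbind(base, self = v$v2, cotwin = v$v1))
})

## complete pairs for one phenotype
.pairValues <- function(x, phenotype) {
  stopifnot(phenotype %in% x@phenotypes)
  p <- x@pairs
  v1 <- p[[paste0(phenotype, "_1")]]
  v2 <- p[[paste0(phenotype, "_2")]]
  ok <- is.finite(v1) & is.finite(v2)
  list(familyId = p$familyId[ok], zygosity = p$zygosity[ok],
       v1 = v1[ok], v2 = v2[ok])
}

setMethod("show", "TwinPairTable", function(object) {
  p <- object@pairs
  cat("TwinPairTable: ", nrow(p), " pairs (",
      sum(p$zygosity == "MZ"), " MZ, ", sum(p$zygosity == "DZ"), " DZ)\n",
      sep = "")
  cat("  phenotypes: ", paste(object@phenotypes, collapse = ", "), "\n",
      sep = "")
})

#' @rdname variance-accessors
#' @export
setMethod("a2", "VarianceFit", function(x) x@a2)

#' @rdname variance-accessors
#' @export
setMethod("c2", "VarianceFit", function(x) x@c2)

#' @rdname variance-accessors
#' @export
setMethod("e2", "VarianceFit", function(x) x@e2)

#' @rdname VarianceFit-class
#' @param object a VarianceFit.
#' @param ... unused.
#' @importFrom stats logLik
#' @export
setMethod("logLik", "VarianceFit", function(object, ...) {
  structure(object@loglik, df = object@npar, class = "logLik")
})

setMethod("show", "VarianceFit", function(object) {
  cat(object@model, " model fit, phenotype '", object@phenotype, "' (",
      object@nMZ, " MZ / ", object@nDZ, " DZ pairs)\n", sep = "")
  cat(sprintf("  a2 = %.3f  c2 = %.3f  e2 = %.3f\n",
              object@a2, object@c2, object@e2))
  if (!all(is.na(object@ciA2)))
    cat(sprintf("  a2 95%% profile CI: (%.3f, %.3f)\n",
                object@ciA2[1], object@ciA2[2]))
  cat(sprintf("  mean = %.3f  total variance = %.3f  logLik = %.3f\n",
              object@mean, object@totalVariance, object@loglik))
  cat("  implied rMZ =", round(object@a2 + object@c2, 3),
      " rDZ =", round(0.5 * object@a2 + object@c2, 3), "\n")
})

setMethod("show", "CholeskyFit", function(object) {
  cat("Trivariate AE Cholesky fit (", object@nMZ, " MZ / ", object@nDZ,
      " DZ pairs), logLik = ", round(object@loglik, 3), "\n", sep = "")
  fmt <- function(M, SE, label) {
    cat(" ", label, "standardized paths (SE):\n")
    for (i in seq_len(nrow(M))) {
      cells <- vapply(seq_len(i), function(j)
        sprintf("%6.3f (%.3f)", M[i, j], SE[i, j]), character(1))
      cat(sprintf("   %-5s %s\n", object@traits[i],
                  paste(cells, collapse = "  ")))
    }
  }
  fmt(object@pathsA, object@seA, "A")
  fmt(object@pathsE, object@seE, "E")
})

setMethod("show", "PowerResult", function(object) {
  cat(sprintf(
    "Power to detect a2 = %.2f (AE model, alpha = %.3f): %.3f\n",
    object@a2True, object@alpha, object@power))
  cat("  ", object@nMZ, " MZ / ", object@nDZ, " DZ pairs; method = ",
      object@method, sep = "")
  if (object@method == "ncp")
    cat(sprintf(" (lambda = %.3f)", object@lambda))
  else
    cat(sprintf(" (%d replicates)", object@nReps))
  if (object@mixture) cat("; 50:50 boundary mixture reference")
  cat("\n")
})

setMethod("show", "ExtremesResult", function(object) {
  cat("Extremes analysis, phenotype '", object@phenotype, "' (probands ",
      object@direction, " ", object@cutoff, ")\n", sep = "")
  cat(sprintf("  N probands: MZ %d, DZ %d%s\n",
              as.integer(object@nProbandsMZ), as.integer(object@nProbandsDZ),
              if (object@singleEntry) " (single entry)" else ""))
  cat(sprintf("  proband mean (SD): MZ %.2f (%.2f), DZ %.2f (%.2f)\n",
              object@probandMeanMZ, object@probandSdMZ,
              object@probandMeanDZ, object@probandSdDZ))
  cat(sprintf("  cotwin  mean (SD): MZ %.2f (%.2f), DZ %.2f (%.2f)\n",
              object@cotwinMeanMZ, object@cotwinSdMZ,
              object@cotwinMeanDZ, object@cotwinSdDZ))
  cat(sprintf("  Welch t = %.2f, df = %.1f, p = %.3f\n",
              object@t, object@df, object@p))
})
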