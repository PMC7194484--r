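## DeFries-Fulker style extremes comparison: select extreme-scoring probands
## and compare how far their cotwins regress toward the population mean in
## MZ versus DZ pairs.

#' Extremes t-test on cotwins of extreme-scoring probands
#'
#' Probands are all twins scoring past the cutoff (below it for
#' `direction = "below"`, above for `"above"`). By the double-entry
#' convention (the default), a pair in which both members qualify
#' contributes both as probands, each bringing the other as cotwin; with
#' `singleEntry = TRUE` each pair contributes at most one proband (the more
#' extreme member, ties to twin 1). Cotwin scores are compared between MZ
#' and DZ groups by a Welch two-sample t-test with Satterthwaite degrees of
#' freedom. Under a genetic aetiology of the extreme, MZ cotwins are
#' expected to regress less toward the population mean than DZ cotwins.
#'
#' @param pairs a [TwinPairTable-class].
#' @param phenotype phenotype name.
#' @param cutoff proband selection threshold (phenotype units).
#' @param direction `"below"` or `"above"`: which tail defines the extreme.
#' @param singleEntry use the single-entry variant.
#' @return An [ExtremesResult-class].
#' @export
extremesTTest <- function(pairs, phenotype = phenotypes(pairs)[1],
                          cutoff, direction = c("below", "above"),
                          singleEntry = FALSE) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  de <- doubleEntry(pairs, phenotype)
  isExtreme <- if (direction == "below") de$self <= cutoff else de$self >= cutoff
  sel <- de[isExtreme, , drop = FALSE]
  if (singleEntry) {
    ## keep the more extreme member of each family (first on ties)
    ord <- order(sel$familyId,
                 if (direction == "below") sel$self else -sel$self)
    sel <- sel[ord, , drop = FALSE]
    sel <- sel[!duplicated(sel$familyId), , drop = FALSE]
  }
  coMZ <- sel$cotwin[sel$zygosity == "MZ"]
  coDZ <- sel$cotwin[sel$zygosity == "DZ"]
  prMZ <- sel$self[sel$zygosity == "MZ"]
  prDZ <- sel$self[sel$zygosity == "DZ"]
  if (length(coMZ) < 2 || length(coDZ) < 2)
    stop("cutoff yields fewer than 2 probands in a zygosity group")
  tt <- t.test(coMZ, coDZ, var.equal = FALSE)
  new("ExtremesResult",
      phenotype = phenotype, cutoff = cutoff, direction = direction,
      nProbandsMZ = length(prMZ), nProbandsDZ = length(prDZ),
      probandMeanMZ = mean(prMZ), probandMeanDZ = mean(prDZ),
      cotwinMeanMZ = mean(coMZ), cotwinMeanDZ = mean(coDZ),
      probandSdMZ = sd(prMZ), probandSdDZ = sd(prDZ),
      cotwinSdMZ = sd(coMZ), cotwinSdDZ = sd(coDZ),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, singleEntry = singleEntry)
}

#' Default proband cutoffs for the study phenotypes
#'
#' Conventional "non-right / non-left-lateralised" thresholds: EHI at or
#' below 4 of 10, QHP at or below 14 of 42, laterality index below 0. The
#' analysis always echoes the cutoff actually used; these are starting
#' points, not inferences.
#'
#' @return named list of `list(cutoff, direction)` per phenotype.
#' @export
extremesDefaultCutoffs <- function() {
  list(ehi = list(cutoff = 4, direction = "below"),
       qhp = list(cutoff = 14, direction = "below"),
       li = list(cutoff = 0, direction = "below"))
}
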