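#' @rdname VelocityRecording-class
#' @param object,x an object.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname VelocityRecording-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname VelocityRecording-class
#' @export
setGeneric("markerTimes", function(x) standardGeneric("markerTimes"))

#' @rdname TrialEpochSet-class
#' @export
setGeneric("accepted", function(x) standardGeneric("accepted"))

#' @rdname TrialEpochSet-class
#' @export
setGeneric("rejectionReason", function(x) standardGeneric("rejectionReason"))

#' @rdname TrialEpochSet-class
#' @export
setGeneric("relTime", function(x) standardGeneric("relTime"))

#' @rdname TrialEpochSet-class
#' @export
setGeneric("trialLI", function(x, ...) standardGeneric("trialLI"))

#' @rdname TwinPairTable-class
#' @export
setGeneric("pairData", function(x) standardGeneric("pairData"))

#' @rdname TwinPairTable-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname TwinPairTable-class
#' @param x a TwinPairTable.
#' @param phenotype phenotype name.
#' @export
setGeneric("doubleEntry", function(x, phenotype) standardGeneric("doubleEntry"))

#' Variance-component accessors
#'
#' Extract the standardized variance proportions from a fitted twin model.
#' @param x a [VarianceFit-class].
#' @return numeric(1) proportion of phenotypic variance.
#' @name variance-accessors
#' @export
setGeneric("a2", function(x) standardGeneric("a2"))

#' @rdname variance-accessors
#' @export
setGeneric("c2", function(x) standardGeneric("c2"))

#' @rdname variance-accessors
#' @export
setGeneric("e2", function(x) standardGeneric("e2"))
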