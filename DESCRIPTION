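Package: twinlat
Title: Twin Analysis of Language Laterality from Functional Transcranial
    Doppler Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing of bilateral cerebral blood-flow-velocity recordings
    from functional transcranial Doppler ultrasound (fTCD) into per-trial and
    per-subject language laterality indices (heart-cycle integration, signal
    normalisation, artefact rejection, epoching, baseline correction), and
    behaviour-genetic analysis of laterality phenotypes in twin samples:
    maximum-likelihood ACE/AE/CE variance decomposition with profile-likelihood
    confidence intervals, trivariate Cholesky AE modelling, DeFries-Fulker
    style extremes t-tests, likelihood-ratio-test power analysis for
    heritability, and split-half reliability. Includes synthetic-data
    generators for twin phenotypes under known variance components and for
    full fTCD sessions with known ground-truth laterality.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
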