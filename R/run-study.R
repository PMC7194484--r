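## End-to-end orchestration: process recordings (or simulate phenotypes),
## assemble the double-entry table, fit twin models, run power and extremes
## analyses, and emit report tables plus a JSON summary.

#' Build a study run configuration
#'
#' All defaults of the processing and analysis stages are visible in the
#' effective configuration that [runStudy()] serialises into its output
#' directory.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed controlling every stochastic stage.
#' @param recordingsDir optional directory of raw recording CSVs (one file
#'   per subject; see [readVelocityRecording()]).
#' @param familiesFile optional CSV mapping subjects to twin pairs, columns
#'   `familyId`, `zygosity`, `subjectId1`, `subjectId2`.
#' @param handednessFile optional CSV with `subjectId`, `ehi`, `qhp`.
#' @param simulateTwins optional named list: phenotype name ->
#'   `list(nMZ, nDZ, a2, c2, marginal)`; used when no recordings are given.
#' @param processing a [ftcdConfig()].
#' @param models phenotypes to fit AE models to; default all available.
#' @param cholesky optional character(3) of phenotypes for the trivariate
#'   AE Cholesky model.
#' @param power list with `nGrid`, `mzFraction`, `a2Values`, `alpha`.
#' @param extremes named list: phenotype -> `list(cutoff, direction)`.
#' @return validated config list of class `"twinlatRunConfig"`.
#' @export
runConfig <- function(outDir, seed = 1,
                      recordingsDir = NULL, familiesFile = NULL,
                      handednessFile = NULL,
                      simulateTwins = NULL,
                      processing = ftcdConfig(),
                      models = NULL, cholesky = NULL,
                      power = list(nGrid = c(50, 100, 150, 200),
                                   mzFraction = 0.5,
                                   a2Values = c(0.15, 0.25, 0.35),
                                   alpha = 0.05),
                      extremes = NULL) {
  for (p in c(recordingsDir, familiesFile, handednessFile))
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  if (is.null(recordingsDir) && is.null(simulateTwins))
    stop("provide either recordingsDir or simulateTwins")
  structure(list(outDir = outDir, seed = as.integer(seed),
                 recordingsDir = recordingsDir,
                 familiesFile = familiesFile,
                 handednessFile = handednessFile,
                 simulateTwins = simulateTwins,
                 processing = processing, models = models,
                 cholesky = cholesky, power = power, extremes = extremes),
            class = "twinlatRunConfig")
}

#' Run the full analysis pipeline
#'
#' Stages: fTCD processing of raw recordings into subject laterality
#' phenotypes (or simulation of twin phenotypes when no recordings are
#' configured); sample-level exclusions; double-entry table assembly;
#' AE-vs-E maximum-likelihood fits with profile intervals and twin-cotwin
#' correlations per phenotype; optional trivariate Cholesky AE model; power
#' table; extremes t-tests. Every numeric output is written under
#' `cfg$outDir` (`subjects.csv`, `trial_lis.csv`, `double_entry.csv`,
#' `heritability.csv`, `cholesky.csv`, `extremes.csv`, `power.csv`,
#' `summary.json`, `effective_config.yaml`, `log.txt`); re-running with the
#' same configuration reproduces all outputs byte for byte.
#'
#' @param cfg a [runConfig()].
#' @return invisible list of in-memory results (`subjects`, `pairs`,
#'   `fits`, `correlations`, `cholesky`, `power`, `extremes`).
#' @export
runStudy <- function(cfg) {
  stopifnot(inherits(cfg, "twinlatRunConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character()
  say <- function(...) {
    msg <- paste0(...)
    logLines <<- c(logLines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  set.seed(cfg$seed)
  yaml::write_yaml(.configAsList(cfg), file.path(cfg$outDir,
                                                 "effective_config.yaml"))
  subjects <- NULL
  pairs <- NULL

  if (!is.null(cfg$recordingsDir)) {
    say("stage ftcd: processing recordings from ", cfg$recordingsDir)
    recs <- stage("ftcd", readVelocityDir(cfg$recordingsDir))
    epochsList <- list()
    subjRows <- list()
    for (id in names(recs)) {
      ep <- stage(paste0("ftcd:", id), {
        pr <- preprocessRecording(recs[[id]], cfg$processing)
        computeTrialLI(epochAndReject(pr, cfg$processing),
                       cfg$processing$poi)
      })
      epochsList[[id]] <- ep
      subjRows[[id]] <- summarizeSubject(ep, cfg$processing$poi,
                                         cfg$processing$minTrials,
                                         cfg$processing$alpha)
    }
    subjects <- do.call(c, unname(subjRows))
    subjects <- applySampleExclusions(subjects, cfg$processing$sdLimit)
    writeTrialLIs(epochsList, file.path(cfg$outDir, "trial_lis.csv"))
    writeSubjectSummaries(subjects, file.path(cfg$outDir, "subjects.csv"),
                          cfg$processing)
    say("stage ftcd: ", length(subjects), " subjects, ",
        sum(as.data.frame(subjects)$excluded), " excluded")
    if (!is.null(cfg$familiesFile)) {
      fam <- read.csv(cfg$familiesFile, stringsAsFactors = FALSE)
      hnd <- if (!is.null(cfg$handednessFile))
        read.csv(cfg$handednessFile, stringsAsFactors = FALSE) else NULL
      pairs <- stage("pairs", buildTwinPairTable(subjects, fam, hnd))
    }
  }

  if (is.null(pairs) && !is.null(cfg$simulateTwins)) {
    say("stage simulate: generating twin phenotypes")
    tabs <- list()
    for (ph in names(cfg$simulateTwins)) {
      s <- cfg$simulateTwins[[ph]]
      tw <- simulateTwinPhenotypes(twinSimConfig(
        s$nMZ, s$nDZ, a2 = s$a2 %||% 0, c2 = s$c2 %||% 0,
        marginal = s$marginal %||% "normal",
        seed = cfg$seed + match(ph, names(cfg$simulateTwins))))
      p <- pairData(tw)
      colnames(p)[colnames(p) == "y_1"] <- paste0(ph, "_1")
      colnames(p)[colnames(p) == "y_2"] <- paste0(ph, "_2")
      tabs[[ph]] <- p
    }
    merged <- Reduce(function(a, b)
      merge(a, b[, setdiff(colnames(b), c("zygosity", "sexPair"))],
            by = "familyId", all = TRUE), tabs)
    pairs <- TwinPairTable(merged, phenotypes = names(cfg$simulateTwins))
  }

  fits <- list(); corrs <- list(); herRows <- list()
  if (!is.null(pairs)) {
    writeTwinPairs(pairs, file.path(cfg$outDir, "double_entry.csv"))
    phs <- cfg$models %||% phenotypes(pairs)
    for (ph in phs) {
      say("stage fit: ", ph)
      ae <- stage(paste0("fit:", ph), fitUnivariate(pairs, ph, model = "AE"))
      e0 <- fitUnivariate(pairs, ph, model = "E")
      lrt <- compareModels(ae, e0)
      ciA <- profileCI(ae, "a2")
      rMZ <- pairCorrelation(pairs, "MZ", ph)
      rDZ <- pairCorrelation(pairs, "DZ", ph)
      fits[[ph]] <- ae
      corrs[[ph]] <- list(MZ = rMZ, DZ = rDZ)
      herRows[[ph]] <- data.frame(
        measure = ph, n_mz = ae@nMZ, n_dz = ae@nDZ,
        r_mz = rMZ$r, r_mz_lo = rMZ$ci[1], r_mz_hi = rMZ$ci[2],
        r_dz = rDZ$r, r_dz_lo = rDZ$ci[1], r_dz_hi = rDZ$ci[2],
        a2 = ae@a2, a2_lo = ciA[1], a2_hi = ciA[2],
        chisq = lrt$chisq, p = lrt$p)
    }
    if (length(herRows))
      write.csv(do.call(rbind, herRows),
                file.path(cfg$outDir, "heritability.csv"), row.names = FALSE)
  }

  chol <- NULL
  if (!is.null(cfg$cholesky) && !is.null(pairs)) {
    say("stage cholesky: ", paste(cfg$cholesky, collapse = ", "))
    chol <- stage("cholesky", fitCholeskyTrivariate(pairs, cfg$cholesky))
    li <- which(lower.tri(diag(3), diag = TRUE), arr.ind = TRUE)
    cholTab <- rbind(
      data.frame(factorType = "A", trait = chol@traits[li[, 1]],
                 factor = li[, 2], estimate = chol@pathsA[li],
                 se = chol@seA[li]),
      data.frame(factorType = "E", trait = chol@traits[li[, 1]],
                 factor = li[, 2], estimate = chol@pathsE[li],
                 se = chol@seE[li]))
    write.csv(cholTab, file.path(cfg$outDir, "cholesky.csv"),
              row.names = FALSE)
  }

  pw <- NULL
  if (!is.null(cfg$power)) {
    say("stage power")
    pw <- stage("power", powerCurve(cfg$power$nGrid,
                                    cfg$power$mzFraction %||% 0.5,
                                    cfg$power$a2Values,
                                    cfg$power$alpha %||% 0.05))
    write.csv(pw, file.path(cfg$outDir, "power.csv"), row.names = FALSE)
  }

  exts <- list()
  if (!is.null(cfg$extremes) && !is.null(pairs)) {
    rows <- list()
    for (ph in names(cfg$extremes)) {
      say("stage extremes: ", ph)
      e <- cfg$extremes[[ph]]
      res <- stage(paste0("extremes:", ph),
                   extremesTTest(pairs, ph, e$cutoff, e$direction))
      exts[[ph]] <- res
      rows[[ph]] <- data.frame(
        phenotype = ph, cutoff = res@cutoff, direction = res@direction,
        n_mz = res@nProbandsMZ, n_dz = res@nProbandsDZ,
        proband_mean_mz = res@probandMeanMZ, proband_sd_mz = res@probandSdMZ,
        proband_mean_dz = res@probandMeanDZ, proband_sd_dz = res@probandSdDZ,
        cotwin_mean_mz = res@cotwinMeanMZ, cotwin_sd_mz = res@cotwinSdMZ,
        cotwin_mean_dz = res@cotwinMeanDZ, cotwin_sd_dz = res@cotwinSdDZ,
        t = res@t, df = res@df, p = res@p)
    }
    write.csv(do.call(rbind, rows), file.path(cfg$outDir, "extremes.csv"),
              row.names = FALSE)
  }

  summary <- list(
    seed = cfg$seed,
    nSubjects = if (!is.null(subjects)) length(subjects) else NA,
    heritability = lapply(fits, function(f)
      list(model = f@model, a2 = f@a2, c2 = f@c2, e2 = f@e2,
           loglik = f@loglik, ciA2 = f@ciA2)),
    power = if (!is.null(pw)) pw else NULL)
  jsonlite::write_json(summary, file.path(cfg$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  writeLines(logLines, file.path(cfg$outDir, "log.txt"))
  invisible(list(subjects = subjects, pairs = pairs, fits = fits,
                 correlations = corrs, cholesky = chol, power = pw,
                 extremes = exts))
}

.configAsList <- function(cfg) {
  out <- unclass(cfg)
  out$processing$poi <- unclass(out$processing$poi)
  out
}
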