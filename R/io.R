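## Readers and writers for the plain-text dialects used by the pipeline:
## raw recording CSVs, per-trial LI tables, subject summaries with a JSON
## provenance sidecar, and long/wide double-entry twin tables.

#' Read a raw fTCD recording from delimited text
#'
#' Expected columns (header required): `time_s`, `left`, `right`, `marker`
#' (non-zero on the sample where a cue to speak occurs) and optionally
#' `trial_valid` (0/1 on marker rows; behavioural validity). Comma and tab
#' delimiters are auto-detected. The sample rate is inferred from the time
#' column and cross-checked against `sampleRate` when given.
#'
#' @param file path to the file.
#' @param subjectId subject identifier; default the file name without
#'   extension.
#' @param sampleRate optional declared sample rate (Hz) to cross-check.
#' @return A [VelocityRecording-class].
#' @export
readVelocityRecording <- function(file, subjectId = NULL, sampleRate = NULL) {
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(file))
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- read.csv(file, sep = sep, stringsAsFactors = FALSE)
  need <- c("time_s", "left", "right", "marker")
  if (!all(need %in% colnames(d)))
    stop("malformed input: expected columns ", paste(need, collapse = ", "))
  mrow <- which(d$marker != 0)
  tv <- if ("trial_valid" %in% colnames(d)) as.logical(d$trial_valid[mrow])
        else rep(TRUE, length(mrow))
  VelocityRecording(subjectId = subjectId, time = d$time_s,
                    left = d$left, right = d$right,
                    markerTime = d$time_s[mrow], trialValid = tv,
                    sampleRate = sampleRate)
}

#' Write a recording in the dialect read by [readVelocityRecording()]
#'
#' @param rec a [VelocityRecording-class].
#' @param file output path.
#' @export
writeVelocityRecording <- function(rec, file) {
  marker <- integer(length(rec@time))
  tvCol <- integer(length(rec@time))
  idx <- round((rec@markerTime - rec@time[1]) * rec@sampleRate) + 1L
  marker[idx] <- seq_along(idx)
  tvCol[idx] <- as.integer(rec@trialValid)
  write.csv(data.frame(time_s = rec@time, left = rec@left,
                       right = rec@right, marker = marker,
                       trial_valid = tvCol),
            file, row.names = FALSE)
  invisible(file)
}

#' Read a directory of per-subject recording files
#'
#' Mirrors a one-file-per-subject deposit layout: every `*.csv`/`*.tsv`
#' file in `dir` is read with [readVelocityRecording()], with the file name
#' (sans extension) as the subject id. Other export dialects can be
#' supported by passing a different `reader`.
#'
#' @param dir directory path.
#' @param pattern file-name regexp, default `"\\.(csv|tsv)$"`.
#' @param reader function(file) -> VelocityRecording; the adapter point for
#'   other dialects.
#' @return named list of [VelocityRecording-class] objects.
#' @export
readVelocityDir <- function(dir, pattern = "\\.(csv|tsv)$",
                            reader = readVelocityRecording) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no recording files found in ", dir)
  recs <- lapply(files, reader)
  names(recs) <- vapply(recs, subjectId, character(1))
  recs
}

#' Write a per-trial laterality-index table
#'
#' One row per trial, columns `subject_id`, `trial_index`, `accepted`,
#' `rejection_reason`, `trial_li_mean`, `trial_li_peak`.
#'
#' @param epochsList list of [TrialEpochSet-class] (per subject), with
#'   per-trial LIs computed.
#' @param file output CSV path.
#' @return the table, invisibly.
#' @export
writeTrialLIs <- function(epochsList, file) {
  rows <- lapply(epochsList, function(ep) {
    rd <- SummarizedExperiment::rowData(ep)
    data.frame(subject_id = S4Vectors::metadata(ep)$subjectId,
               trial_index = rd$trialIndex,
               accepted = rd$accepted,
               rejection_reason = rd$rejectionReason,
               trial_li_mean = rd$liMean,
               trial_li_peak = rd$liPeak,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Write subject summaries with a JSON provenance sidecar
#'
#' All [SubjectLaterality-class] fields as CSV; the processing
#' configuration is serialised to `<file>.json` alongside.
#'
#' @param subjects a [SubjectLaterality-class].
#' @param file output CSV path.
#' @param cfg the [ftcdConfig()] used, embedded in the sidecar.
#' @return the data.frame written, invisibly.
#' @export
writeSubjectSummaries <- function(subjects, file, cfg = ftcdConfig()) {
  d <- as.data.frame(subjects)
  write.csv(d, file, row.names = FALSE)
  jsonlite::write_json(cfg, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(d)
}

#' Read a long-format (double-entry compatible) twin phenotype CSV
#'
#' Expected columns: `family_id`, `zygosity`, `twin_order` (1/2), optional
#' `sex`, plus one column per phenotype. Double-entered files (each pair in
#' both orders) are de-duplicated on `(family_id, twin_order)`.
#'
#' @param file path to the CSV.
#' @param phenotypes phenotype column names; default every column other
#'   than the structural ones.
#' @return A [TwinPairTable-class].
#' @export
readTwinPairs <- function(file, phenotypes = NULL) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("family_id", "zygosity", "twin_order")
  if (!all(need %in% colnames(d)))
    stop("expected columns ", paste(need, collapse = ", "))
  if (is.null(phenotypes))
    phenotypes <- setdiff(colnames(d), c(need, "sex"))
  d <- d[!duplicated(d[, c("family_id", "twin_order")]), , drop = FALSE]
  fams <- unique(d$family_id)
  rows <- lapply(fams, function(f) {
    df <- d[d$family_id == f, , drop = FALSE]
    t1 <- df[df$twin_order == 1, , drop = FALSE]
    t2 <- df[df$twin_order == 2, , drop = FALSE]
    out <- data.frame(familyId = f, zygosity = df$zygosity[1],
                      sexPair = if ("sex" %in% colnames(df))
                        paste0(sort(df$sex), collapse = "") else NA_character_,
                      stringsAsFactors = FALSE)
    for (ph in phenotypes) {
      out[[paste0(ph, "_1")]] <- if (nrow(t1)) t1[[ph]][1] else NA_real_
      out[[paste0(ph, "_2")]] <- if (nrow(t2)) t2[[ph]][1] else NA_real_
    }
    out
  })
  TwinPairTable(do.call(rbind, rows), phenotypes = phenotypes)
}

#' Write a twin table as long-format CSV
#'
#' @param pairs a [TwinPairTable-class].
#' @param file output path.
#' @param doubleEntry when TRUE (default) every pair is written twice, once
#'   per twin ordering, the convention used for symmetric pair statistics.
#' @return the data.frame written, invisibly.
#' @export
writeTwinPairs <- function(pairs, file, doubleEntry = TRUE) {
  p <- pairData(pairs)
  phs <- phenotypes(pairs)
  long <- function(ord) {
    o <- data.frame(family_id = p$familyId, zygosity = p$zygosity,
                    twin_order = ord, stringsAsFactors = FALSE)
    for (ph in phs) o[[ph]] <- p[[paste0(ph, "_", ord)]]
    o
  }
  out <- rbind(long(1L), long(2L))
  if (doubleEntry) {
    swap <- out
    swap$twin_order <- 3L - swap$twin_order
    swap$entry <- 2L
    out$entry <- 1L
    out <- rbind(out, swap)
  }
  out <- out[order(out$family_id, out$twin_order), , drop = FALSE]
  write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Assemble a twin pair table from subject summaries and a family map
#'
#' Joins per-subject laterality summaries onto a family structure and
#' propagates subject-level exclusions to the pair level: when either
#' member of a pair is excluded for a phenotype, the pair's values for the
#' laterality phenotypes are set to NA (listwise within phenotype), the
#' behaviour used for the study-style analysis.
#'
#' @param subjects a [SubjectLaterality-class] (after
#'   [applySampleExclusions()]).
#' @param families data.frame with columns `familyId`, `zygosity`,
#'   `subjectId1`, `subjectId2` and optionally `sexPair`.
#' @param handedness optional data.frame with `subjectId`, `ehi`, `qhp`.
#' @return A [TwinPairTable-class] with phenotypes `li_mean`, `li_peak`,
#'   `binary_typical` (1 typical / 0 atypical), `mean_left_flow`,
#'   `mean_right_flow`, plus `ehi`/`qhp` when supplied.
#' @export
buildTwinPairTable <- function(subjects, families, handedness = NULL) {
  d <- as.data.frame(subjects)
  get <- function(ids, col) d[[col]][match(ids, d$subjectId)]
  exc1 <- get(families$subjectId1, "excluded")
  exc2 <- get(families$subjectId2, "excluded")
  excPair <- ifelse(is.na(exc1), TRUE, exc1) | ifelse(is.na(exc2), TRUE, exc2)
  out <- data.frame(familyId = families$familyId,
                    zygosity = families$zygosity,
                    sexPair = if ("sexPair" %in% colnames(families))
                      families$sexPair else NA_character_,
                    stringsAsFactors = FALSE)
  liCols <- c(li_mean = "liMean", li_peak = "liPeak",
              mean_left_flow = "meanLeftFlow",
              mean_right_flow = "meanRightFlow")
  for (k in names(liCols)) {
    v1 <- get(families$subjectId1, liCols[[k]])
    v2 <- get(families$subjectId2, liCols[[k]])
    v1[excPair] <- NA_real_; v2[excPair] <- NA_real_
    out[[paste0(k, "_1")]] <- v1
    out[[paste0(k, "_2")]] <- v2
  }
  bt <- function(ids) as.numeric(get(ids, "binaryTypical") == "typical")
  b1 <- bt(families$subjectId1); b2 <- bt(families$subjectId2)
  b1[excPair] <- NA_real_; b2[excPair] <- NA_real_
  out$binary_typical_1 <- b1; out$binary_typical_2 <- b2
  phs <- c(names(liCols), "binary_typical")
  if (!is.null(handedness)) {
    for (ph in intersect(c("ehi", "qhp"), colnames(handedness))) {
      out[[paste0(ph, "_1")]] <-
        handedness[[ph]][match(families$subjectId1, handedness$subjectId)]
      out[[paste0(ph, "_2")]] <-
        handedness[[ph]][match(families$subjectId2, handedness$subjectId)]
      phs <- c(phs, ph)
    }
  }
  TwinPairTable(out, phenotypes = phs)
}
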