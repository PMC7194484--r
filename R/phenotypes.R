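## Handedness instrument scoring: Edinburgh Handedness Inventory (10
## demonstration items) and Quantification of Hand Preference (21 card
## trials, 3 per each of 7 spatial positions).

#' Score the Edinburgh Handedness Inventory
#'
#' Ten demonstrated actions, each coded `"right"`, `"left"` or `"either"`.
#' One point is awarded for exclusive right-hand use, half a point when both
#' hands were used, zero for left-hand use; the score ranges 0-10 in steps
#' of 0.5. Missing items (NA) are prorated to the full 10-item scale and
#' flagged via the `"prorated"` attribute.
#'
#' @param responses character vector of 10 item responses in
#'   `{"right", "left", "either"}` (NA allowed for missing items).
#' @return numeric(1) score in `[0, 10]`; attribute `prorated` is TRUE when
#'   any item was missing.
#' @export
scoreEHI <- function(responses) {
  if (length(responses) != 10L)
    stop("EHI requires exactly 10 item responses, got ", length(responses))
  pts <- .scoreItems(responses,
                     c(right = 1, either = 0.5, left = 0), "EHI")
  .proratedSum(pts, fullItems = 10L, label = "EHI")
}

#' Score the Quantification of Hand Preference task
#'
#' Twenty-one card trials (three at each of seven positions), each coded
#' `"right"`, `"left"` or `"transfer"` (card moved from one hand to the
#' other). Two points for right-handed use, one for a transfer, zero for
#' left-handed use; the score ranges 0-42. Missing trials are prorated to
#' the 21-trial scale and flagged.
#'
#' @param responses character vector of 21 trial responses in
#'   `{"right", "left", "transfer"}` (NA allowed).
#' @param positions optional integer vector of card positions (1-7), one per
#'   trial; when supplied, the 3-per-position layout is checked.
#' @return numeric(1) score in `[0, 42]`; attribute `prorated` as for
#'   [scoreEHI()].
#' @export
scoreQHP <- function(responses, positions = NULL) {
  if (length(responses) != 21L)
    stop("QHP requires exactly 21 trial responses, got ", length(responses))
  if (!is.null(positions)) {
    if (length(positions) != 21L || !all(positions %in% 1:7) ||
        !all(table(factor(positions, levels = 1:7)) == 3L))
      stop("QHP positions must place exactly 3 trials at each of positions 1-7")
  }
  pts <- .scoreItems(responses,
                     c(right = 2, transfer = 1, left = 0), "QHP")
  .proratedSum(pts, fullItems = 21L, label = "QHP")
}

.scoreItems <- function(responses, map, label) {
  responses <- as.character(responses)
  known <- responses %in% names(map) | is.na(responses)
  if (!all(known))
    stop(label, ": invalid response value(s): ",
         paste(unique(responses[!known]), collapse = ", "))
  unname(map[responses])
}

.proratedSum <- function(pts, fullItems, label) {
  nObs <- sum(!is.na(pts))
  if (nObs == 0L) stop(label, ": all items missing")
  score <- sum(pts, na.rm = TRUE) * fullItems / nObs
  structure(score, prorated = nObs < fullItems)
}

#' Read item-level handedness responses and score them
#'
#' Wide-format CSV, one row per subject: a `subjectId` column plus
#' `ehi_1` ... `ehi_10` and/or `qhp_1` ... `qhp_21` item columns.
#'
#' @param file path to the CSV.
#' @return data.frame with `subjectId` and the available scores `ehi`,
#'   `qhp`, plus logical `ehiProrated`/`qhpProrated` flags.
#' @export
readItemResponses <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  stopifnot("subjectId" %in% colnames(d))
  out <- data.frame(subjectId = as.character(d$subjectId),
                    stringsAsFactors = FALSE)
  ehiCols <- paste0("ehi_", 1:10)
  if (all(ehiCols %in% colnames(d))) {
    sc <- lapply(seq_len(nrow(d)), function(i)
      scoreEHI(unlist(d[i, ehiCols], use.names = FALSE)))
    out$ehi <- vapply(sc, as.numeric, numeric(1))
    out$ehiProrated <- vapply(sc, attr, logical(1), "prorated")
  }
  qhpCols <- paste0("qhp_", 1:21)
  if (all(qhpCols %in% colnames(d))) {
    sc <- lapply(seq_len(nrow(d)), function(i)
      scoreQHP(unlist(d[i, qhpCols], use.names = FALSE)))
    out$qhp <- vapply(sc, as.numeric, numeric(1))
    out$qhpProrated <- vapply(sc, attr, logical(1), "prorated")
  }
  out
}
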