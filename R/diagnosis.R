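# Risk stratification (Sanz/PETHEMA-GIMEMA) and the advisory diagnostic
# opinion derived from classified cell counts.

#' Sanz/PETHEMA-GIMEMA risk stratification from a CBC panel
#'
#' high: WBC > 10 x10^9/L; low: WBC <= 10 and platelets > 40 x10^9/L;
#' intermediate: WBC <= 10 and platelets <= 40 (thresholds inclusive as
#' printed in the score definition).
#'
#' @param cbc a \linkS4class{CBCPanel}.
#' @return \code{"low"}, \code{"intermediate"} or \code{"high"}.
#' @examples
#' stratifyRisk(cbcPanel(wbc = 2.1, platelets = 63))    # low
#' stratifyRisk(cbcPanel(wbc = 7.3, platelets = 27))    # intermediate
#' stratifyRisk(cbcPanel(wbc = 25.5, platelets = 16))   # high
#' @export
stratifyRisk <- function(cbc) {
  stopifnot(is(cbc, "CBCPanel"))
  validObject(cbc)
  if (cbc@wbc > 10) "high"
  else if (cbc@platelets > 40) "low"
  else "intermediate"
}

#' Summarize classified cell counts
#'
#' @param counts named (or ordered) integer 6-vector of per-class cell counts
#'   in \code{LEUKOCYTE_CLASSES} order.
#' @param nFields number of visual fields examined (default NA).
#' @return List with \code{counts}, \code{nFields}, \code{total} and
#'   \code{promyelocyteFraction} (0 when no cells were counted).
#' @examples
#' cellCountSummary(c(0, 0, 19, 4, 23, 103), nFields = 153)
#' @export
cellCountSummary <- function(counts, nFields = NA_integer_) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 6L, all(counts >= 0L))
  names(counts) <- LEUKOCYTE_CLASSES
  total <- sum(counts)
  list(counts = counts, nFields = nFields, total = total,
       promyelocyteFraction =
         if (total == 0L) 0 else unname(counts["promyelocyte"]) / total)
}

.TREATMENT <- c(low = "ATRA + arsenic",
                intermediate = "ATRA + arsenic",
                high = "ATRA + arsenic + chemotherapy induction")

#' Render an advisory diagnostic opinion
#'
#' APL is suspected when at least \code{minPromyelocytes} cells were
#' classified as promyelocytes. A suspected case carries a risk-dependent
#' advisory treatment string ("ATRA + arsenic" for low/intermediate risk,
#' "ATRA + arsenic + chemotherapy induction" for high risk); otherwise the
#' treatment is empty. All opinions carry a fixed not-for-clinical-use
#' disclaimer.
#'
#' @param summary a cell count summary from \code{\link{cellCountSummary}}.
#' @param risk risk tag from \code{\link{stratifyRisk}}.
#' @param minPromyelocytes positivity threshold (default 1: any promyelocyte
#'   flags suspicion).
#' @param note optional extra note appended to the disclaimer.
#' @return A \linkS4class{DiagnosticOpinion}.
#' @examples
#' s <- cellCountSummary(c(0, 0, 5, 0, 90, 3))
#' renderOpinion(s, "high")
#' @export
renderOpinion <- function(summary, risk, minPromyelocytes = 1L, note = NULL) {
  stopifnot(risk %in% c("low", "intermediate", "high"),
            minPromyelocytes >= 1L)
  suspected <- unname(summary$counts["promyelocyte"]) >= minPromyelocytes
  new("DiagnosticOpinion",
      suspectedApl = suspected,
      risk = risk,
      potentialTreatment = if (suspected) unname(.TREATMENT[risk]) else "",
      evidence = summary,
      note = c(.notForClinicalUse, note))
}

#' Export a diagnostic opinion as JSON
#'
#' @param opinion a \linkS4class{DiagnosticOpinion}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeOpinion <- function(opinion, path) {
  jsonlite::write_json(
    list(suspected_apl = opinion@suspectedApl,
         risk = opinion@risk,
         potential_treatment = opinion@potentialTreatment,
         counts = as.list(opinion@evidence$counts),
         n_fields = opinion@evidence$nFields,
         promyelocyte_fraction = opinion@evidence$promyelocyteFraction,
         note = paste(opinion@note, collapse = " ")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
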