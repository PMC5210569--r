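## S4 classes for the SAP database, the gamma fit and the cascade report.

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues; sequences are validated against this set.
#' @keywords internal
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Default accession prefix marking decoy entries
#' @keywords internal
.DECOY_PREFIX <- "DECOY_"

#' SapDatabase: a target + decoy protein database carrying SAP provenance
#'
#' Holds the concatenated target (wild-type and variant) and decoy
#' protein entries of a theoretical SAP database.  Sequences live in an
#' [Biostrings::AAStringSet] (one entry per accession); per-entry
#' metadata live in a parallel [S4Vectors::DataFrame] with columns:
#'
#' \describe{
#'   \item{accession}{unique entry accession; variant entries follow the
#'     scheme \code{<parent>|SAP|<ref><pos><alt>|<source_id>} and decoy
#'     entries carry the \code{DECOY_} prefix}
#'   \item{is_variant}{entry carries a single amino-acid substitution}
#'   \item{is_decoy}{entry is a reversed decoy}
#'   \item{parent_accession}{wild-type parent (variants) or source entry
#'     (decoys); \code{NA} for wild-type targets}
#'   \item{position, ref_aa, alt_aa, source_id, source_db}{the SAP, in
#'     1-based protein coordinates of the (un-reversed) target entry;
#'     \code{NA} for non-variant entries}
#'   \item{aliases}{[IRanges::CharacterList] of accessions merged away
#'     by exact-sequence deduplication}
#' }
#'
#' @slot sequences [Biostrings::AAStringSet] of protein sequences.
#' @slot entryInfo [S4Vectors::DataFrame] of per-entry metadata,
#'   parallel to \code{sequences}.
#'
#' @seealso [buildSapDatabase()], [entryInfo()], [sapTable()],
#'   [targetEntries()], [decoyEntries()]
#' @export
setClass("SapDatabase",
         slots = c(sequences = "AAStringSet",
                   entryInfo = "DFrame"))

setValidity("SapDatabase", function(object) {
  seqs <- object@sequences
  info <- object@entryInfo
  msgs <- character()
  needed <- c("accession", "is_variant", "is_decoy", "parent_accession",
              "position", "ref_aa", "alt_aa", "source_id", "source_db",
              "aliases")
  if (!all(needed %in% colnames(info)))
    msgs <- c(msgs, paste("entryInfo must have columns:",
                          paste(setdiff(needed, colnames(info)), collapse = ", ")))
  else {
    if (nrow(info) != length(seqs))
      msgs <- c(msgs, "entryInfo and sequences have different lengths")
    if (anyDuplicated(info$accession))
      msgs <- c(msgs, "accessions are not unique")
    if (length(seqs) && !identical(names(seqs), as.character(info$accession)))
      msgs <- c(msgs, "names(sequences) must equal entryInfo$accession")
    if (any(width(seqs) == 0L))
      msgs <- c(msgs, "empty protein sequence")
    iv <- info$is_variant & !info$is_decoy
    if (any(iv & (is.na(info$position) | is.na(info$ref_aa) | is.na(info$alt_aa))))
      msgs <- c(msgs, "variant entries must carry position/ref_aa/alt_aa")
  }
  if (length(msgs)) msgs else TRUE
})

#' GammaFit: linear model of the mutation fraction among false hits
#'
#' The subgroup ("transferred") FDR for mutation peptides scales the
#' global FDR by \eqn{\gamma_k(x)}, the probability that a false
#' identification with score above \eqn{x} lands on a mutation-carrying
#' peptide.  \eqn{\gamma_k(x)} is approximated by a straight line
#' \eqn{a x + b} whose coefficients are estimated from the decoy PSM
#' population (the observable model of false identifications).
#'
#' @slot a slope of the fitted line (per score unit).
#' @slot b intercept of the fitted line.
#' @slot scoreGrid numeric cell boundaries over the decoy score range.
#' @slot cellScore mean decoy score per retained cell (regression
#'   abscissa).
#' @slot gammaObserved observed decoy mutation fraction per cell.
#' @slot cellCounts decoy PSMs per retained cell.
#' @slot fallback \code{TRUE} when the data were too sparse for a slope
#'   and a constant fit (a = 0, pooled fraction) was used.
#' @slot mode \code{"binned"} (per-cell fractions) or
#'   \code{"cumulative"} (fractions above each threshold).
#'
#' @seealso [fitGamma()], [predictGamma()], [transferredFdr()]
#' @export
setClass("GammaFit",
         slots = c(a = "numeric", b = "numeric",
                   scoreGrid = "numeric", cellScore = "numeric",
                   gammaObserved = "numeric", cellCounts = "integer",
                   fallback = "logical", mode = "character"))

setValidity("GammaFit", function(object) {
  msgs <- character()
  if (length(object@a) != 1L || !is.finite(object@a))
    msgs <- c(msgs, "slope a must be a finite scalar")
  if (length(object@b) != 1L || !is.finite(object@b))
    msgs <- c(msgs, "intercept b must be a finite scalar")
  if (is.unsorted(object@scoreGrid, strictly = TRUE))
    msgs <- c(msgs, "scoreGrid must be strictly increasing")
  if (length(object@gammaObserved) &&
      (any(object@gammaObserved < 0) || any(object@gammaObserved > 1)))
    msgs <- c(msgs, "observed fractions must lie in [0, 1]")
  if (length(object@gammaObserved) != length(object@cellScore) ||
      length(object@gammaObserved) != length(object@cellCounts))
    msgs <- c(msgs, "cellScore, gammaObserved and cellCounts must be parallel")
  if (length(msgs)) msgs else TRUE
})

#' CascadeReport: per-stage retention counts of the QC cascade
#'
#' One row per cascade stage with the number of distinct peptides,
#' proteins and spectra retained after that stage, plus the terminal
#' bucket each candidate peptide ended in (retained, too_short, non_sap,
#' unmapped, wildtype_collision, failed_group_fdr, ptm_collision).
#'
#' @slot stages data.frame with columns stage, peptides, proteins,
#'   spectra (counts retained after each stage, in cascade order).
#' @slot buckets named integer vector of terminal peptide buckets.
#'
#' @seealso [runCascade()], [renderCascadeReport()]
#' @export
setClass("CascadeReport",
         slots = c(stages = "data.frame", buckets = "integer"))

setValidity("CascadeReport", function(object) {
  st <- object@stages
  msgs <- character()
  if (!all(c("stage", "peptides", "proteins", "spectra") %in% colnames(st)))
    msgs <- c(msgs, "stages needs columns stage, peptides, proteins, spectra")
  else {
    if (any(st$peptides < 0) || any(st$proteins < 0) || any(st$spectra < 0))
      msgs <- c(msgs, "negative counts")
    if (is.unsorted(rev(st$peptides)))
      msgs <- c(msgs, "peptide counts must be non-increasing across stages")
  }
  if (length(msgs)) msgs else TRUE
})
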