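## Missense annotation of coding SNVs against transcript models.

#' TranscriptModel: a CDS model for variant annotation
#'
#' Minimal transcript representation needed to map a genomic SNV onto a
#' codon: the chromosome, strand, ordered CDS segments (1-based closed
#' genomic intervals, ascending genomic order) and the CDS nucleotide
#' sequence in transcript (5'->3') orientation, stop codon excluded.
#'
#' @slot transcriptId transcript identifier.
#' @slot proteinAccession accession of the encoded protein.
#' @slot chrom chromosome name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot segments [IRanges::IRanges] of CDS segments in ascending
#'   genomic order.
#' @slot cdsSequence CDS nucleotide string, transcript orientation.
#' @export
setClass("TranscriptModel",
         slots = c(transcriptId = "character",
                   proteinAccession = "character",
                   chrom = "character",
                   strand = "character",
                   segments = "IRanges",
                   cdsSequence = "character"))

setValidity("TranscriptModel", function(object) {
  msgs <- character()
  if (!object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  tot <- sum(width(object@segments))
  if (tot %% 3L != 0L)
    msgs <- c(msgs, "total CDS length must be a multiple of 3")
  if (nchar(object@cdsSequence) != tot)
    msgs <- c(msgs, "cdsSequence length must equal total segment length")
  if (length(object@segments) > 1L &&
      is.unsorted(start(object@segments), strictly = TRUE))
    msgs <- c(msgs, "segments must be in ascending genomic order")
  if (tot > 0L) {
    aa <- .translate_cds(object@cdsSequence)
    if (grepl("*", aa, fixed = TRUE))
      msgs <- c(msgs, "CDS translation contains a stop codon")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn TranscriptModel-class constructor.
#' @param transcriptId,proteinAccession,chrom,strand,cdsSequence see
#'   slots.
#' @param segments an [IRanges::IRanges] or a 2-column matrix of
#'   (start, end) genomic intervals.
#' @export
transcriptModel <- function(transcriptId, proteinAccession, chrom, strand,
                            segments, cdsSequence) {
  if (is.matrix(segments))
    segments <- IRanges(start = segments[, 1L], end = segments[, 2L])
  new("TranscriptModel", transcriptId = transcriptId,
      proteinAccession = proteinAccession, chrom = chrom, strand = strand,
      segments = segments, cdsSequence = toupper(cdsSequence))
}

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@transcriptId,
      sprintf("(%s, %s strand, %d segment(s), %d nt -> %s)\n",
              object@chrom, object@strand, length(object@segments),
              nchar(object@cdsSequence), object@proteinAccession))
})

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.translate_cds <- function(nt) {
  codons <- substring(nt, seq(1L, nchar(nt), by = 3L),
                      seq(3L, nchar(nt), by = 3L))
  paste(unname(GENETIC_CODE[codons]), collapse = "")
}

## Genomic position -> 1-based CDS offset (transcript orientation).
## Returns NA when the position falls outside every segment.
.cds_offset <- function(tx, pos) {
  st <- start(tx@segments); en <- end(tx@segments); w <- en - st + 1L
  i <- which(pos >= st & pos <= en)
  if (length(i) != 1L) return(NA_integer_)
  if (tx@strand == "+") {
    before <- if (i > 1L) sum(w[seq_len(i - 1L)]) else 0L
    before + (pos - st[i] + 1L)
  } else {
    after <- if (i < length(w)) sum(w[seq.int(i + 1L, length(w))]) else 0L
    after + (en[i] - pos + 1L)
  }
}

#' Annotate a coding SNV as missense, synonymous or stop-gain
#'
#' Maps a genomic single-nucleotide variant onto the codon it falls in
#' (reverse-complementing the alleles for minus-strand transcripts),
#' translates the reference and mutated codon, and returns a SAP record
#' when the change is missense.  Synonymous changes return no record;
#' stop-gains are skipped too (a truncation, not a single amino-acid
#' substitution); in both cases the result has zero rows and the
#' consequence label is attached as \code{attr(, "consequence")}.
#'
#' Errors are signalled with classed conditions so batch callers can
#' tally them: \code{sapQC_non_coding} when the position lies outside
#' every CDS segment and \code{sapQC_reference_mismatch} when the
#' variant's reference base disagrees with the CDS sequence.
#'
#' @param variant list or one-row data.frame with \code{chrom},
#'   \code{pos}, \code{ref_base}, \code{alt_base}, \code{source_id} and
#'   optionally \code{source_db}.
#' @param transcript a [TranscriptModel-class].
#' @param proteome optional named character vector or
#'   [Biostrings::AAStringSet]; when it contains the transcript's
#'   protein, the reference residue is cross-checked against it.
#' @return for missense changes, a one-row data.frame (a SAP record)
#'   with \code{protein_accession}, \code{position}, \code{ref_aa},
#'   \code{alt_aa}, \code{source_id}, \code{source_db}; otherwise a
#'   zero-row data.frame with the consequence in
#'   \code{attr(, "consequence")}.
#' @examples
#' tx <- transcriptModel("T1", "P1", "chr1", "+",
#'                       cbind(101, 109), "ATGGCCAAA")
#' v <- list(chrom = "chr1", pos = 105, ref_base = "C", alt_base = "T",
#'           source_id = "rs1")
#' annotateMissense(v, tx)   # GCC -> GTC: Ala2Val
#' @export
annotateMissense <- function(variant, transcript, proteome = NULL) {
  ref <- toupper(as.character(variant$ref_base))
  alt <- toupper(as.character(variant$alt_base))
  if (nchar(ref) != 1L || nchar(alt) != 1L ||
      !ref %in% names(.COMPLEMENT) || !alt %in% names(.COMPLEMENT))
    stop(.condition("sapQC_not_snv",
                    "only single-nucleotide substitutions are annotated"))
  if (ref == alt)
    stop(.condition("sapQC_not_snv", "ref and alt base are identical"))
  if (!is.null(variant$chrom) &&
      as.character(variant$chrom) != transcript@chrom)
    stop(.condition("sapQC_non_coding",
                    "variant chromosome does not match the transcript"))
  off <- .cds_offset(transcript, as.integer(variant$pos))
  if (is.na(off))
    stop(.condition("sapQC_non_coding", "variant lies outside the CDS"))
  minus <- transcript@strand == "-"
  ref_t <- if (minus) .COMPLEMENT[[ref]] else ref
  alt_t <- if (minus) .COMPLEMENT[[alt]] else alt
  codon_i <- (off + 2L) %/% 3L
  in_codon <- off - 3L * (codon_i - 1L)
  codon <- substr(transcript@cdsSequence, 3L * codon_i - 2L, 3L * codon_i)
  if (substr(codon, in_codon, in_codon) != ref_t)
    stop(.condition("sapQC_reference_mismatch", sprintf(
      "reference base mismatch at CDS offset %d (expected %s, CDS has %s)",
      off, ref_t, substr(codon, in_codon, in_codon))))
  mcodon <- codon
  substr(mcodon, in_codon, in_codon) <- alt_t
  ref_aa <- GENETIC_CODE[[codon]]
  alt_aa <- GENETIC_CODE[[mcodon]]
  consequence <-
    if (identical(ref_aa, alt_aa)) "synonymous"
    else if (identical(alt_aa, "*")) "stop_gain"
    else "missense"
  if (consequence != "missense") {
    out <- .empty_sap_table()
    attr(out, "consequence") <- consequence
    return(out)
  }
  acc <- transcript@proteinAccession
  if (!is.null(proteome) && acc %in% names(proteome)) {
    pseq <- as.character(proteome[[acc]])
    if (substr(pseq, codon_i, codon_i) != ref_aa)
      stop(.condition("sapQC_reference_mismatch", sprintf(
        "protein %s has %s at %d, CDS encodes %s",
        acc, substr(pseq, codon_i, codon_i), codon_i, ref_aa)))
  }
  out <- data.frame(protein_accession = acc, position = codon_i,
                    ref_aa = ref_aa, alt_aa = alt_aa,
                    source_id = as.character(variant$source_id),
                    source_db = if (is.null(variant$source_db)) "unknown"
                                else as.character(variant$source_db),
                    stringsAsFactors = FALSE)
  attr(out, "consequence") <- "missense"
  out
}

#' Batch missense annotation with a consequence summary
#'
#' Runs [annotateMissense()] over a variant table, collecting the
#' missense SAP records and tallying every other outcome (synonymous,
#' stop_gain, non_coding, reference_mismatch, not_snv) instead of
#' stopping, the way genome-scale annotators report their skip reasons.
#'
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref_base}, \code{alt_base}, \code{source_id}, optional
#'   \code{source_db} and \code{transcript_id}.
#' @param transcripts named list of [TranscriptModel-class] objects;
#'   looked up by the variant's \code{transcript_id} when present,
#'   otherwise every variant is tried against every transcript on its
#'   chromosome (first CDS hit wins).
#' @param proteome optional, see [annotateMissense()].
#' @return list with \code{saps} (data.frame of SAP records),
#'   \code{consequence} (character vector parallel to \code{variants})
#'   and \code{summary} (named counts).
#' @export
annotateVariants <- function(variants, transcripts, proteome = NULL) {
  n <- nrow(variants)
  cons <- character(n)
  saps <- vector("list", n)
  byChrom <- NULL
  if (is.null(variants$transcript_id)) {
    chroms <- vapply(transcripts, function(t) t@chrom, character(1L))
    byChrom <- split(transcripts, chroms)
  }
  for (i in seq_len(n)) {
    v <- lapply(variants, `[`, i)
    txs <- if (!is.null(v$transcript_id)) transcripts[as.character(v$transcript_id)]
           else byChrom[[as.character(v$chrom)]]
    res <- NULL; lab <- "non_coding"
    for (tx in txs) {
      lab <- tryCatch({
        res <- annotateMissense(v, tx, proteome)
        attr(res, "consequence")
      },
      sapQC_non_coding = function(e) "non_coding",
      sapQC_reference_mismatch = function(e) "reference_mismatch",
      sapQC_not_snv = function(e) "not_snv")
      if (lab != "non_coding") break
    }
    cons[i] <- lab
    if (lab == "missense") saps[[i]] <- res
  }
  saps <- do.call(rbind, saps[!vapply(saps, is.null, logical(1L))])
  if (is.null(saps)) saps <- .empty_sap_table()
  rownames(saps) <- NULL
  list(saps = saps, consequence = cons,
       summary = table(factor(cons, levels = c("missense", "synonymous",
                                               "stop_gain", "non_coding",
                                               "reference_mismatch",
                                               "not_snv"))))
}

.empty_sap_table <- function() {
  data.frame(protein_accession = character(), position = integer(),
             ref_aa = character(), alt_aa = character(),
             source_id = character(), source_db = character(),
             stringsAsFactors = FALSE)
}

.condition <- function(class, msg) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = sys.call(-1L)))
}
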