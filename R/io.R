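## Readers and writers: FASTA databases, variant TSV/VCF, transcript
## tables, PSM tables, SAP tables.  All tabular writers prepend '#'
## provenance header lines (config hash, seed, tool version); readers
## skip them.

.provenance_lines <- function(config = NULL) {
  ver <- as.character(utils::packageVersion("sapQC"))
  lines <- sprintf("#tool=sapQC %s", ver)
  if (!is.null(config))
    lines <- c(lines,
               sprintf("#config_hash=%s", .config_hash(config)),
               sprintf("#seed=%d", config$seed))
  lines
}

.write_tsv <- function(tab, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.provenance_lines(config), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Read a wild-type proteome from FASTA
#'
#' Accessions are the first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return [Biostrings::AAStringSet] named by accession.
#' @export
readProteomeFasta <- function(path) {
  seqs <- readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a SAP database (targets + decoys) to FASTA
#'
#' Headers carry the accession plus \code{parent=} / \code{source=}
#' description fields for variant entries, so provenance survives FASTA
#' round-trips; [readSapDatabaseFasta()] reconstructs the
#' [SapDatabase-class] from them.
#'
#' @param db a [SapDatabase-class].
#' @param path output FASTA file.
#' @export
writeSapDatabaseFasta <- function(db, path) {
  info <- entryInfo(db)
  seqs <- proteinSequences(db)
  desc <- ifelse(info$is_variant,
                 sprintf(" parent=%s source=%s pos=%d ref=%s alt=%s",
                         info$parent_accession, info$source_db,
                         info$position, info$ref_aa, info$alt_aa),
                 "")
  names(seqs) <- paste0(info$accession, desc)
  writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' @describeIn writeSapDatabaseFasta read the database back.
#' @param decoyTag accession prefix marking decoys.
#' @return a [SapDatabase-class].
#' @export
readSapDatabaseFasta <- function(path, decoyTag = .DECOY_PREFIX) {
  seqs <- readAAStringSet(path)
  headers <- names(seqs)
  acc <- sub("\\s.*$", "", headers)
  names(seqs) <- acc
  field <- function(key) {
    m <- regmatches(headers, regexpr(paste0(key, "=[^ ]+"), headers))
    out <- rep(NA_character_, length(headers))
    out[grepl(paste0(key, "="), headers)] <- sub(paste0(key, "="), "", m)
    out
  }
  parent <- field("parent")
  is_decoy <- startsWith(acc, decoyTag)
  is_variant <- !is.na(parent) | grepl("|SAP|", acc, fixed = TRUE)
  pos <- suppressWarnings(as.integer(field("pos")))
  info <- DataFrame(accession = acc, is_variant = is_variant,
                    is_decoy = is_decoy,
                    parent_accession = ifelse(is_decoy, sub(decoyTag, "", acc,
                                                            fixed = TRUE),
                                              parent),
                    position = pos, ref_aa = field("ref"),
                    alt_aa = field("alt"),
                    source_id = .sap_accession_field(acc, 4L),
                    source_db = field("source"),
                    aliases = CharacterList(rep(list(character()),
                                                length(acc))))
  new("SapDatabase", sequences = seqs, entryInfo = info)
}

## split a variant accession parent|SAP|A123V|src and return field k
.sap_accession_field <- function(acc, k) {
  parts <- strsplit(acc, "|", fixed = TRUE)
  vapply(parts, function(p) if (length(p) >= k && "SAP" %in% p) p[k]
                            else NA_character_, character(1L))
}

#' Read / write variant tables (TSV and VCF subset)
#'
#' The TSV carries columns \code{chrom}, \code{pos}, \code{ref_base},
#' \code{alt_base}, \code{source_id} and optionally \code{source_db}
#' and \code{transcript_id}.  The VCF form is the fixed-column v4
#' subset (CHROM, POS, ID, REF, ALT); only single-nucleotide records
#' are returned, others are dropped with a message.
#'
#' @param path input file.
#' @return data.frame of variant records.
#' @export
readVariantTsv <- function(path) {
  tab <- .read_tsv(path)
  need <- c("chrom", "pos", "ref_base", "alt_base", "source_id")
  if (!all(need %in% names(tab)))
    stop("variant TSV needs columns: ", paste(need, collapse = ", "))
  tab$pos <- as.integer(tab$pos)
  tab
}

#' @describeIn readVariantTsv write the TSV form.
#' @param variants data.frame of variant records.
#' @param config optional [sapConfig()] for the provenance header.
#' @export
writeVariantTsv <- function(variants, path, config = NULL)
  .write_tsv(variants, path, config = config)

#' @describeIn readVariantTsv read the VCF v4 subset.
#' @param sourceDb provenance label stored in \code{source_db}.
#' @export
readVariantVcf <- function(path, sourceDb = "vcf") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(), pos = integer(),
                      ref_base = character(), alt_base = character(),
                      source_id = character(), source_db = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 5L)) stop("malformed VCF record(s)")
  tab <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    pos = as.integer(vapply(parts, `[`, "", 2L)),
                    source_id = vapply(parts, `[`, "", 3L),
                    ref_base = toupper(vapply(parts, `[`, "", 4L)),
                    alt_base = toupper(vapply(parts, `[`, "", 5L)),
                    stringsAsFactors = FALSE)
  snv <- nchar(tab$ref_base) == 1L & nchar(tab$alt_base) == 1L &
    tab$ref_base %in% names(.COMPLEMENT) & tab$alt_base %in% names(.COMPLEMENT)
  if (any(!snv))
    message(sum(!snv), " non-SNV record(s) dropped")
  tab <- tab[snv, c("chrom", "pos", "ref_base", "alt_base", "source_id")]
  tab$source_db <- sourceDb
  rownames(tab) <- NULL
  tab
}

#' @describeIn readVariantTsv write the VCF v4 subset.
#' @export
writeVariantVcf <- function(variants, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                       variants$chrom, variants$pos, variants$source_id,
                       variants$ref_base, variants$alt_base), con)
  invisible(path)
}

#' Read / write transcript model tables
#'
#' The tabular form has columns \code{transcript_id},
#' \code{protein_accession}, \code{chrom}, \code{strand} and
#' \code{cds_segments} (comma-separated \code{start-end} genomic
#' intervals); CDS nucleotide sequences (transcript orientation) come
#' from a companion FASTA keyed by transcript id.
#'
#' @param path transcript table TSV.
#' @param cdsFasta CDS FASTA file.
#' @return named list of [TranscriptModel-class] objects.
#' @export
readTranscriptTable <- function(path, cdsFasta) {
  tab <- .read_tsv(path)
  cds <- readDNAStringSet(cdsFasta)
  names(cds) <- sub("\\s.*$", "", names(cds))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    segs <- do.call(rbind, lapply(
      strsplit(tab$cds_segments[i], ",", fixed = TRUE)[[1L]],
      function(s) as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])))
    transcriptModel(tab$transcript_id[i], tab$protein_accession[i],
                    tab$chrom[i], tab$strand[i], segs,
                    as.character(cds[[tab$transcript_id[i]]]))
  })
  setNames(out, tab$transcript_id)
}

#' @describeIn readTranscriptTable write the table + CDS FASTA.
#' @param transcripts named list of [TranscriptModel-class] objects.
#' @param config optional [sapConfig()] for the provenance header.
#' @export
writeTranscriptTable <- function(transcripts, path, cdsFasta,
                                 config = NULL) {
  tab <- do.call(rbind, lapply(transcripts, function(tx)
    data.frame(transcript_id = tx@transcriptId,
               protein_accession = tx@proteinAccession,
               chrom = tx@chrom, strand = tx@strand,
               cds_segments = paste(start(tx@segments), end(tx@segments),
                                    sep = "-", collapse = ","),
               stringsAsFactors = FALSE)))
  .write_tsv(tab, path, config = config)
  cds <- DNAStringSet(vapply(transcripts, function(tx) tx@cdsSequence, ""))
  names(cds) <- vapply(transcripts, function(tx) tx@transcriptId, "")
  writeXStringSet(cds, cdsFasta, width = 70L)
  invisible(path)
}

#' Read / write PSM tables
#'
#' Required columns: \code{spectrum_id}, \code{peptide}, \code{score},
#' \code{charge}, \code{proteins} (';'-separated accessions).  A
#' missing \code{is_decoy} column is inferred from the decoy accession
#' prefix (a PSM is decoy when all its accessions are decoys).
#'
#' @param path TSV file.
#' @param decoyTag decoy accession prefix for inference.
#' @return data.frame of PSMs.
#' @export
readPsmTable <- function(path, decoyTag = .DECOY_PREFIX) {
  tab <- .read_tsv(path)
  need <- c("spectrum_id", "peptide", "score", "charge", "proteins")
  if (!all(need %in% names(tab)))
    stop("PSM table needs columns: ", paste(need, collapse = ", "))
  if (!"is_decoy" %in% names(tab))
    tab$is_decoy <- vapply(strsplit(as.character(tab$proteins), ";",
                                    fixed = TRUE),
                           function(a) all(startsWith(a, decoyTag)),
                           logical(1L))
  tab$is_decoy <- as.logical(tab$is_decoy)
  if ("is_mutation" %in% names(tab))
    tab$is_mutation <- as.logical(tab$is_mutation)
  tab$score <- as.numeric(tab$score)
  tab
}

#' @describeIn readPsmTable write a PSM table.
#' @param psms data.frame of PSMs.
#' @param config optional [sapConfig()] for the provenance header.
#' @export
writePsmTable <- function(psms, path, config = NULL)
  .write_tsv(psms, path, config = config)

#' Write a SAP table (one row per substitution)
#'
#' TSV with \code{protein_accession}, \code{position}, \code{ref_aa},
#' \code{alt_aa}, \code{source_id}, \code{source_db} and an
#' \code{isobaric_flag} column marking substitutions whose residue-mass
#' difference is within \code{toleranceDa} (see [flagIsobaric()]).
#'
#' @param saps data.frame of SAP records.
#' @param path output TSV.
#' @param toleranceDa isobaric flag tolerance in Da.
#' @param config optional [sapConfig()] for the provenance header.
#' @export
writeSapTable <- function(saps, path, toleranceDa = 0.05, config = NULL) {
  if (is.null(saps$source_db)) saps$source_db <- "unknown"
  saps$isobaric_flag <- flagIsobaric(saps$ref_aa, saps$alt_aa, toleranceDa)
  .write_tsv(saps, path, config = config)
}

#' @describeIn writeSapTable read it back.
#' @export
readSapTable <- function(path) .read_tsv(path)

#' Write the final SAP peptide table
#'
#' @param saps SAP peptide table (from [mapSapPeptides()] /
#'   [runCascade()]).
#' @param path output TSV.
#' @param config optional [sapConfig()] for the provenance header.
#' @export
writeSapPeptideTable <- function(saps, path, config = NULL)
  .write_tsv(saps, path, config = config)
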