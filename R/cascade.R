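## The QC cascade: global FDR -> length -> SAP mapping -> wild-type
## exclusion -> group FDR -> PTM split -> protein reassembly.

#' Retain target PSMs passing the global FDR criterion
#'
#' Keeps target PSMs with \code{q_value <=} \code{qMax} (boundary
#' inclusive); decoys are dropped from downstream reporting.
#'
#' @param psms scored PSM table (see [computeQvalues()]).
#' @param qMax q-value cutoff, default 0.01.
#' @return filtered PSM table.
#' @export
filterGlobalFdr <- function(psms, qMax = 0.01) {
  stopifnot("q_value" %in% names(psms))
  psms[!psms$is_decoy & psms$q_value <= qMax, , drop = FALSE]
}

#' Retain peptides longer than a minimum length
#'
#' SAP detection screens out short peptides: only peptides strictly
#' longer than \code{minExclusive} residues (default 9, i.e. at least
#' 10-mers) are kept — short peptides map too promiscuously to call a
#' single-residue variant.
#'
#' @param psms PSM table with a \code{peptide} column.
#' @param minExclusive exclusive length bound, default 9.
#' @return filtered table.
#' @export
filterLength <- function(psms, minExclusive = 9L) {
  psms[nchar(psms$peptide) > minExclusive, , drop = FALSE]
}

#' Map identified peptides onto SAP sites of the variant database
#'
#' For each identified peptide, finds every variant target entry that
#' contains it as an exact substring; the peptide is called a SAP
#' peptide only when some occurrence covers the entry's SAP position
#' (in which case the peptide necessarily carries the alternative
#' residue at the variant offset).  Peptides matching variant entries
#' only outside the SAP span are non-SAP; peptides matching no database
#' entry at all are flagged unmapped (stale database).  The wild-type
#' counterpart (variant residue reverted to the reference amino acid)
#' is computed for every SAP peptide.
#'
#' Peptides occurring in several variant entries with the same
#' substitution collapse into one row with all accessions; distinct
#' substitutions yield distinct rows.
#'
#' @param psms filtered target PSM table.
#' @param database a [SapDatabase-class].
#' @return data.frame (one row per SAP peptide x substitution) with
#'   columns \code{peptide}, \code{accessions} (';'-separated),
#'   \code{protein_accession} (first parent), \code{position},
#'   \code{ref_aa}, \code{alt_aa}, \code{source_id},
#'   \code{variant_offset}, \code{wildtype_peptide}, \code{n_spectra},
#'   \code{spectrum_ids}, \code{q_value}, \code{group_q_value},
#'   \code{status}; attributes \code{non_sap} and \code{unmapped} list
#'   the other peptides.
#' @export
mapSapPeptides <- function(psms, database) {
  stopifnot(is(database, "SapDatabase"))
  info <- entryInfo(database)
  tset <- proteinSequences(database)[!info$is_decoy]
  vsel <- info$is_variant & !info$is_decoy
  vseqs <- proteinSequences(database)[vsel]
  vinfo <- info[vsel, , drop = FALSE]
  peptides <- unique(as.character(psms$peptide))
  rows <- vector("list", length(peptides))
  non_sap <- character(0); unmapped <- character(0)
  tchar <- as.character(tset)
  haystack <- paste(tchar, collapse = "$")
  for (pi in seq_along(peptides)) {
    p <- peptides[pi]
    hits <- which(vcountPattern(p, vseqs) > 0L)
    covering <- list()
    for (h in hits) {
      spos <- vinfo$position[h]
      m <- matchPattern(p, vseqs[[h]])
      st <- start(m)
      ok <- st <= spos & (st + nchar(p) - 1L) >= spos
      if (!any(ok)) next
      off <- spos - st[ok][1L] + 1L
      stopifnot(substr(p, off, off) == vinfo$alt_aa[h])
      key <- paste(vinfo$ref_aa[h], off, vinfo$alt_aa[h], sep = "_")
      covering[[key]] <- rbind(covering[[key]],
        data.frame(accession = vinfo$accession[h],
                   parent = vinfo$parent_accession[h],
                   position = spos, ref_aa = vinfo$ref_aa[h],
                   alt_aa = vinfo$alt_aa[h],
                   source_id = vinfo$source_id[h],
                   variant_offset = off, stringsAsFactors = FALSE))
    }
    if (!length(covering)) {
      if (length(hits) || grepl(p, haystack, fixed = TRUE))
        non_sap <- c(non_sap, p)
      else unmapped <- c(unmapped, p)
      next
    }
    sub <- psms[psms$peptide == p, , drop = FALSE]
    rows[[pi]] <- do.call(rbind, lapply(covering, function(g) {
      wt <- p
      substr(wt, g$variant_offset[1L], g$variant_offset[1L]) <- g$ref_aa[1L]
      data.frame(peptide = p,
                 accessions = paste(g$accession, collapse = ";"),
                 protein_accession = g$parent[1L],
                 position = g$position[1L],
                 ref_aa = g$ref_aa[1L], alt_aa = g$alt_aa[1L],
                 source_id = paste(unique(g$source_id), collapse = ";"),
                 variant_offset = g$variant_offset[1L],
                 wildtype_peptide = wt,
                 n_spectra = length(unique(sub$spectrum_id)),
                 spectrum_ids = paste(unique(sub$spectrum_id), collapse = ";"),
                 q_value = if ("q_value" %in% names(sub)) min(sub$q_value)
                           else NA_real_,
                 group_q_value = NA_real_,
                 status = "retained", stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) out <- .empty_sap_peptide_table()
  rownames(out) <- NULL
  attr(out, "non_sap") <- non_sap
  attr(out, "unmapped") <- unmapped
  out
}

.empty_sap_peptide_table <- function() {
  data.frame(peptide = character(), accessions = character(),
             protein_accession = character(), position = integer(),
             ref_aa = character(), alt_aa = character(),
             source_id = character(), variant_offset = integer(),
             wildtype_peptide = character(), n_spectra = integer(),
             spectrum_ids = character(), q_value = numeric(),
             group_q_value = numeric(), status = character(),
             stringsAsFactors = FALSE)
}

## TRUE for each peptide that occurs as an exact substring of any
## sequence in `proteome` (named character / AAStringSet).
.in_proteome <- function(peptides, proteome, ilEquivalence = FALSE) {
  seqs <- if (is(proteome, "XStringSet")) as.character(proteome)
          else as.character(proteome)
  if (ilEquivalence) {
    seqs <- chartr("I", "L", seqs)
    peptides <- chartr("I", "L", peptides)
  }
  haystack <- paste(seqs, collapse = "$")   # '$' never occurs in proteins
  vapply(peptides, function(p) grepl(p, haystack, fixed = TRUE), logical(1L),
         USE.NAMES = FALSE)
}

#' Exclude SAP peptides that also exist in the wild-type proteome
#'
#' A candidate variant peptide whose full sequence occurs verbatim
#' anywhere in the wild-type protein database cannot be claimed as
#' evidence for the variant — it is moved to status
#' \code{wildtype_collision}.  With \code{ilEquivalence} the comparison
#' treats isoleucine and leucine as identical (they are isobaric and
#' indistinguishable by standard MS/MS).
#'
#' @param saps SAP peptide table from [mapSapPeptides()].
#' @param wildtypeProteome named character vector or
#'   [Biostrings::AAStringSet] of wild-type proteins.
#' @param ilEquivalence treat I and L as the same residue (default
#'   off).
#' @return the table with \code{status} updated.
#' @export
excludeWildtypeCollisions <- function(saps, wildtypeProteome,
                                      ilEquivalence = FALSE) {
  if (!nrow(saps)) return(saps)
  idx <- saps$status == "retained"
  hit <- .in_proteome(saps$peptide[idx], wildtypeProteome, ilEquivalence)
  saps$status[idx][hit] <- "wildtype_collision"
  saps
}

## substitutions indistinguishable from common PTMs (deamidation)
.PTM_MIMICS <- data.frame(ref_aa = c("N", "Q"), alt_aa = c("D", "E"),
                          ptm = c("deamidation(N)", "deamidation(Q)"),
                          stringsAsFactors = FALSE)

#' Split off SAP peptides that collide with known PTM peptides
#'
#' A SAP call is indistinguishable from a post-translational
#' modification when its wild-type counterpart is a known PTM-bearing
#' peptide (classically deamidation, Asn->Asp).  Such peptides are
#' moved to status \code{ptm_collision} — kept as a separate output for
#' review rather than deleted.  With \code{builtinRules} the bundled
#' PTM-mimic substitutions (N->D, Q->E) are additionally flagged in a
#' \code{ptm_mimic} column (flag only, no exclusion).
#'
#' @param saps SAP peptide table.
#' @param ptmPeptides character vector of known PTM peptide sequences
#'   (compared against the wild-type counterparts).
#' @param builtinRules also flag deamidation-mimicking substitutions.
#' @return the table with \code{status} (and optionally
#'   \code{ptm_mimic}) updated.
#' @export
excludePtmCollisions <- function(saps, ptmPeptides = character(),
                                 builtinRules = FALSE) {
  if (builtinRules)
    saps$ptm_mimic <- paste(saps$ref_aa, saps$alt_aa) %in%
      paste(.PTM_MIMICS$ref_aa, .PTM_MIMICS$alt_aa)
  if (!nrow(saps) || !length(ptmPeptides)) return(saps)
  idx <- saps$status == "retained" & saps$wildtype_peptide %in% ptmPeptides
  saps$status[idx] <- "ptm_collision"
  saps
}

#' Reassemble variant proteins from retained SAP peptides
#'
#' Groups retained SAP peptides by variant protein accession and
#' reports each protein supported by at least \code{minPeptides}
#' peptides, with its peptide and spectrum support counts.
#'
#' @param saps SAP peptide table.
#' @param minPeptides minimum retained peptides per protein (default
#'   1).
#' @return data.frame with \code{accession}, \code{n_peptides},
#'   \code{n_spectra}, \code{peptides}.
#' @export
reassembleProteins <- function(saps, minPeptides = 1L) {
  ret <- saps[saps$status == "retained", , drop = FALSE]
  if (!nrow(ret))
    return(data.frame(accession = character(), n_peptides = integer(),
                      n_spectra = integer(), peptides = character(),
                      stringsAsFactors = FALSE))
  acc <- strsplit(ret$accessions, ";", fixed = TRUE)
  long <- data.frame(accession = unlist(acc),
                     peptide = rep(ret$peptide, lengths(acc)),
                     n_spectra = rep(ret$n_spectra, lengths(acc)),
                     stringsAsFactors = FALSE)
  grp <- split(long, long$accession)
  out <- do.call(rbind, lapply(grp, function(g)
    data.frame(accession = g$accession[1L],
               n_peptides = length(unique(g$peptide)),
               n_spectra = sum(g$n_spectra),
               peptides = paste(unique(g$peptide), collapse = ";"),
               stringsAsFactors = FALSE)))
  out <- out[out$n_peptides >= minPeptides, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full SAP quality-control cascade
#'
#' Executes, in order: target-decoy q-values and the global FDR filter
#' (\code{q <= qMax}); the peptide length filter (> 9 residues); SAP
#' site mapping against the variant database; wild-type collision
#' exclusion; the subgroup (transferred) FDR filter on the mutation
#' subgroup; the PTM collision split; and protein reassembly.  Counts
#' of distinct peptides, proteins and spectra retained after each stage
#' are collected into a [CascadeReport-class].  The run is
#' deterministic given its inputs and configuration.
#'
#' Mutation labels for the group FDR: target PSMs are
#' mutation-carrying when their peptide was mapped to a SAP site (and
#' survived wild-type exclusion); decoy PSMs when any assigned
#' accession is a decoy derived from a variant entry.  A pre-existing
#' \code{is_mutation} column (e.g. from [simulatePsms()]) is used
#' as-is.
#'
#' @param psms PSM table (see [readPsmTable()] for the column
#'   contract).
#' @param database a [SapDatabase-class].
#' @param wildtypeProteome wild-type proteins for collision exclusion;
#'   defaults to the database's non-variant target entries.
#' @param ptmPeptides known PTM peptide sequences.
#' @param config a [sapConfig()] list of tunables.
#' @return list with \code{sapPeptides} (retained), \code{ptm} (PTM
#'   collision bucket), \code{excluded} (all other terminal rows),
#'   \code{proteins} (reassembled), \code{report}
#'   ([CascadeReport-class]), \code{gammaFit}, \code{psms} (scored
#'   table) and \code{diagnostics} (unmapped peptides).
#' @export
runCascade <- function(psms, database, wildtypeProteome = NULL,
                       ptmPeptides = character(), config = sapConfig()) {
  stopifnot(is(database, "SapDatabase"))
  if (is.null(wildtypeProteome)) {
    info <- entryInfo(database)
    wildtypeProteome <-
      proteinSequences(database)[!info$is_decoy & !info$is_variant]
  }
  scored <- if ("q_value" %in% names(psms)) psms else computeQvalues(psms)
  stage <- function(tab) {
    prot <- unlist(strsplit(as.character(tab$proteins), ";", fixed = TRUE))
    c(peptides = length(unique(tab$peptide)),
      proteins = length(unique(prot)),
      spectra = length(unique(tab$spectrum_id)))
  }
  targets <- scored[!scored$is_decoy, , drop = FALSE]
  s0 <- stage(targets)
  f1 <- filterGlobalFdr(scored, qMax = config$q_max)
  s1 <- stage(f1)
  f2 <- filterLength(f1, minExclusive = config$min_peptide_length_exclusive)
  s2 <- stage(f2)
  map <- mapSapPeptides(f2, database)
  sap_stage <- function(tab) {
    ret <- tab[tab$status == "retained", , drop = FALSE]
    c(peptides = length(unique(ret$peptide)),
      proteins = length(unique(unlist(strsplit(ret$accessions, ";",
                                               fixed = TRUE)))),
      spectra = length(unique(unlist(strsplit(ret$spectrum_ids, ";",
                                              fixed = TRUE)))))
  }
  s3 <- sap_stage(map)
  map <- excludeWildtypeCollisions(map, wildtypeProteome,
                                   ilEquivalence = config$il_equivalence)
  s4 <- sap_stage(map)
  ## group (transferred) FDR on the mutation subgroup
  if (!"is_mutation" %in% names(scored)) {
    sap_pep <- unique(map$peptide[map$status == "retained"])
    dec_var <- entryInfo(database)$accession[entryInfo(database)$is_decoy &
                                             entryInfo(database)$is_variant]
    scored$is_mutation <- ifelse(
      scored$is_decoy,
      vapply(strsplit(as.character(scored$proteins), ";", fixed = TRUE),
             function(a) any(a %in% dec_var), logical(1L)),
      scored$peptide %in% sap_pep)
  }
  fit <- fitGamma(scored)
  scored <- groupQvalues(scored, fit)
  gq <- tapply(scored$group_q_value[!scored$is_decoy],
               scored$peptide[!scored$is_decoy],
               function(v) suppressWarnings(min(v, na.rm = TRUE)))
  map$group_q_value <- as.numeric(gq[map$peptide])
  fail <- map$status == "retained" &
    (!is.finite(map$group_q_value) | map$group_q_value > config$group_q_max)
  map$status[fail] <- "failed_group_fdr"
  s5 <- sap_stage(map)
  map <- excludePtmCollisions(map, ptmPeptides,
                              builtinRules = config$ptm_builtin_rules)
  s6 <- sap_stage(map)
  proteins <- reassembleProteins(map,
                                 minPeptides = config$min_peptides_per_protein)
  s7 <- c(peptides = s6[["peptides"]], proteins = nrow(proteins),
          spectra = s6[["spectra"]])
  stages <- data.frame(
    stage = c("input_targets", "global_fdr", "length_filter", "sap_mapping",
              "wildtype_exclusion", "group_fdr", "ptm_split", "reassembly"),
    rbind(s0, s1, s2, s3, s4, s5, s6, s7), row.names = NULL,
    stringsAsFactors = FALSE)
  universe <- unique(f1$peptide)
  too_short <- setdiff(universe, unique(f2$peptide))
  buckets <- c(retained = sum(map$status == "retained"),
               too_short = length(too_short),
               non_sap = length(attr(map, "non_sap")),
               unmapped = length(attr(map, "unmapped")),
               wildtype_collision = sum(map$status == "wildtype_collision"),
               failed_group_fdr = sum(map$status == "failed_group_fdr"),
               ptm_collision = sum(map$status == "ptm_collision"))
  report <- new("CascadeReport", stages = stages,
                buckets = as.integer(buckets) |> setNames(names(buckets)))
  list(sapPeptides = map[map$status == "retained", , drop = FALSE],
       ptm = map[map$status == "ptm_collision", , drop = FALSE],
       excluded = map[!map$status %in% c("retained", "ptm_collision"), ,
                      drop = FALSE],
       proteins = proteins, report = report, gammaFit = fit,
       psms = scored,
       diagnostics = list(unmapped = attr(map, "unmapped"),
                          non_sap = attr(map, "non_sap")))
}

## ---- CascadeReport methods --------------------------------------------

#' @rdname CascadeReport-class
#' @export
setMethod("cascadeStages", "CascadeReport", function(report) report@stages)

#' @rdname CascadeReport-class
#' @export
setMethod("cascadeBuckets", "CascadeReport", function(report) report@buckets)

setMethod("show", "CascadeReport", function(object) {
  cat("CascadeReport (peptides / proteins / spectra retained per stage)\n")
  st <- object@stages
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %-20s %8d %8d %8d\n", st$stage[i], st$peptides[i],
                st$proteins[i], st$spectra[i]))
  b <- object@buckets
  cat("  terminal peptide buckets:",
      paste(names(b), b, sep = "=", collapse = ", "), "\n")
})

#' Render a cascade report as a table with per-stage deltas
#'
#' Produces the per-stage retention table (peptides, proteins, spectra
#' and the peptide delta versus the previous stage) and optionally
#' writes it as TSV with a provenance header; [readCascadeReport()]
#' round-trips the file.
#'
#' @param report a [CascadeReport-class].
#' @param file optional path to write a TSV.
#' @param config optional [sapConfig()] recorded in the file header.
#' @return the rendered data.frame, invisibly when writing.
#' @export
renderCascadeReport <- function(report, file = NULL, config = NULL) {
  st <- cascadeStages(report)
  st$peptide_delta <- c(0L, diff(st$peptides))
  b <- cascadeBuckets(report)
  bdf <- data.frame(stage = paste0("bucket:", names(b)), peptides = unname(b),
                    proteins = NA_integer_, spectra = NA_integer_,
                    peptide_delta = NA_integer_, stringsAsFactors = FALSE)
  out <- rbind(st, bdf)
  if (!is.null(file)) {
    .write_tsv(out, file, config = config)
    return(invisible(out))
  }
  out
}

#' @describeIn renderCascadeReport read a rendered report back into a
#'   [CascadeReport-class].
#' @param path TSV written by \code{renderCascadeReport}.
#' @export
readCascadeReport <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  isb <- startsWith(tab$stage, "bucket:")
  st <- tab[!isb, c("stage", "peptides", "proteins", "spectra")]
  rownames(st) <- NULL
  b <- setNames(as.integer(tab$peptides[isb]),
                sub("^bucket:", "", tab$stage[isb]))
  new("CascadeReport", stages = st, buckets = b)
}
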