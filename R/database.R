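## SAP protein database construction: substitution, deduplication,
## decoys, assembly into a SapDatabase.

#' Protein-notation string of a SAP (e.g. "A673V")
#'
#' @param refAa,altAa single-letter residues.
#' @param position 1-based residue index.
#' @return character vector like \code{"A673V"}.
#' @export
sapNotation <- function(refAa, position, altAa)
  paste0(refAa, position, altAa)

#' Apply a single amino-acid substitution to a protein
#'
#' Replaces the residue at the SAP position with the alternative amino
#' acid and derives a provenance-preserving accession of the form
#' \code{<parent>|SAP|<ref><pos><alt>|<source_id>}.  If the parent
#' sequence does not carry the expected reference residue at that
#' position (a stale annotation, e.g. after a proteome update), the SAP
#' is dropped with a warning and \code{NULL} is returned.
#'
#' @param parent a length-1 named character vector (name = accession)
#'   or a length-1 [Biostrings::AAStringSet].
#' @param sap one-row data.frame or list with \code{position},
#'   \code{ref_aa}, \code{alt_aa}, \code{source_id}.
#' @return length-1 named character vector (the variant entry), or
#'   \code{NULL} when the annotation is stale.
#' @examples
#' applySap(c(P1 = "MKT"), list(position = 2, ref_aa = "K",
#'                              alt_aa = "R", source_id = "rs1"))
#' @export
applySap <- function(parent, sap) {
  if (is(parent, "XStringSet")) parent <- setNames(as.character(parent),
                                                   names(parent))
  stopifnot(length(parent) == 1L, !is.null(names(parent)))
  seq <- unname(parent)
  pos <- as.integer(sap$position)
  stopifnot(pos >= 1L, pos <= nchar(seq))
  if (substr(seq, pos, pos) != sap$ref_aa) {
    warning(sprintf(
      "stale annotation: %s has '%s' at %d, expected '%s'; SAP dropped",
      names(parent), substr(seq, pos, pos), pos, sap$ref_aa))
    return(NULL)
  }
  substr(seq, pos, pos) <- as.character(sap$alt_aa)
  acc <- paste(names(parent), "SAP",
               sapNotation(sap$ref_aa, pos, sap$alt_aa),
               sap$source_id, sep = "|")
  setNames(seq, acc)
}

#' Exact-sequence deduplication with alias bookkeeping
#'
#' Removes entries whose sequence is an exact duplicate of an earlier
#' entry; the survivor (first in input order) records the merged-away
#' accessions in its \code{aliases} metadata column.  The operation is
#' idempotent and order-stable.
#'
#' @param sequences named character vector or
#'   [Biostrings::AAStringSet]; existing \code{aliases} metadata (from a
#'   previous pass) are carried along.
#' @return [Biostrings::AAStringSet] of survivors with an
#'   \code{aliases} [IRanges::CharacterList] in \code{mcols()}.
#' @export
mergeAndDedupe <- function(sequences) {
  prior <- NULL
  if (is(sequences, "XStringSet")) {
    if (!is.null(mcols(sequences)) && "aliases" %in% colnames(mcols(sequences)))
      prior <- as.list(mcols(sequences)$aliases)
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(prior)) prior <- rep(list(character()), length(sequences))
  grp <- match(sequences, sequences)        # index of first occurrence
  keep <- which(grp == seq_along(sequences))
  aliases <- lapply(keep, function(i) {
    dups <- which(grp == i & seq_along(grp) != i)
    unique(c(prior[[i]], names(sequences)[dups],
             unlist(prior[dups], use.names = FALSE)))
  })
  out <- AAStringSet(sequences[keep])
  mcols(out) <- DataFrame(aliases = CharacterList(aliases))
  out
}

#' Reversed-decoy database generation
#'
#' One decoy per target entry: the full reversal of the target sequence,
#' with the accession prefixed by a fixed decoy tag.  Reversal preserves
#' entry count, lengths and amino-acid composition, giving the decoy
#' population the same gross statistics as the targets.
#'
#' @param sequences named character vector or
#'   [Biostrings::AAStringSet] of target entries.
#' @param prefix decoy accession prefix (default \code{"DECOY_"}).
#' @return [Biostrings::AAStringSet] of decoy entries.
#' @examples
#' as.character(buildDecoys(c(P1 = "MKTR")))   # DECOY_P1 = "RTKM"
#' @export
buildDecoys <- function(sequences, prefix = .DECOY_PREFIX) {
  if (!is(sequences, "XStringSet")) sequences <- AAStringSet(sequences)
  out <- reverse(sequences)
  names(out) <- paste0(prefix, names(sequences))
  out
}

#' Default decoy accession prefix
#' @return the accession prefix marking decoy entries.
#' @export
decoyPrefix <- function() .DECOY_PREFIX

#' Build a target + decoy SAP protein database
#'
#' Applies every SAP record to its parent protein ([applySap()]),
#' appends the variant entries to the wild-type proteome, removes exact
#' duplicate sequences ([mergeAndDedupe()]; wild-type entries come
#' first, so they win ties against variants) and generates one reversed
#' decoy per surviving target ([buildDecoys()]).
#'
#' @param proteome named character vector or [Biostrings::AAStringSet]
#'   of wild-type proteins.
#' @param saps data.frame of SAP records with columns
#'   \code{protein_accession}, \code{position}, \code{ref_aa},
#'   \code{alt_aa}, \code{source_id} and optionally \code{source_db}.
#' @param decoyTag decoy accession prefix.
#' @return a [SapDatabase-class].
#' @export
buildSapDatabase <- function(proteome, saps, decoyTag = .DECOY_PREFIX) {
  if (is(proteome, "XStringSet")) proteome <- setNames(as.character(proteome),
                                                       names(proteome))
  stopifnot(!is.null(names(proteome)), !anyDuplicated(names(proteome)))
  if (is.null(saps$source_db)) saps$source_db <- "unknown"
  missing_parent <- !saps$protein_accession %in% names(proteome)
  if (any(missing_parent)) {
    warning(sum(missing_parent), " SAP record(s) reference unknown proteins; dropped")
    saps <- saps[!missing_parent, , drop = FALSE]
  }
  vseqs <- character(0); vmeta <- vector("list", nrow(saps))
  for (i in seq_len(nrow(saps))) {
    sap <- lapply(saps, `[`, i)
    ent <- applySap(proteome[sap$protein_accession], sap)
    if (is.null(ent)) next
    vseqs[names(ent)] <- ent
    vmeta[[i]] <- data.frame(accession = names(ent),
                             parent_accession = sap$protein_accession,
                             position = as.integer(sap$position),
                             ref_aa = sap$ref_aa, alt_aa = sap$alt_aa,
                             source_id = as.character(sap$source_id),
                             source_db = as.character(sap$source_db),
                             stringsAsFactors = FALSE)
  }
  vmeta <- do.call(rbind, vmeta[!vapply(vmeta, is.null, logical(1L))])
  ## duplicate variant accessions (same SAP from the same source) collapse
  if (!is.null(vmeta) && anyDuplicated(vmeta$accession)) {
    vmeta <- vmeta[!duplicated(vmeta$accession), , drop = FALSE]
  }
  targets <- mergeAndDedupe(c(proteome, vseqs))
  tinfo <- .entry_info_for(names(targets), vmeta,
                           aliases = mcols(targets)$aliases,
                           is_decoy = FALSE)
  decoys <- buildDecoys(targets, prefix = decoyTag)
  dinfo <- tinfo
  dinfo$accession <- names(decoys)
  dinfo$parent_accession <- tinfo$accession
  dinfo$is_decoy <- TRUE
  dinfo$aliases <- CharacterList(rep(list(character()), length(decoys)))
  allseqs <- c(targets, decoys)
  mcols(allseqs) <- NULL
  info <- rbind(tinfo, dinfo)
  rownames(info) <- NULL
  new("SapDatabase", sequences = allseqs, entryInfo = info)
}

.entry_info_for <- function(accessions, vmeta, aliases, is_decoy) {
  m <- if (is.null(vmeta)) rep(NA_integer_, length(accessions))
       else match(accessions, vmeta$accession)
  DataFrame(accession = accessions,
            is_variant = !is.na(m),
            is_decoy = rep(is_decoy, length(accessions)),
            parent_accession = if (is.null(vmeta)) NA_character_
                               else vmeta$parent_accession[m],
            position = if (is.null(vmeta)) NA_integer_ else vmeta$position[m],
            ref_aa = if (is.null(vmeta)) NA_character_ else vmeta$ref_aa[m],
            alt_aa = if (is.null(vmeta)) NA_character_ else vmeta$alt_aa[m],
            source_id = if (is.null(vmeta)) NA_character_ else vmeta$source_id[m],
            source_db = if (is.null(vmeta)) NA_character_ else vmeta$source_db[m],
            aliases = aliases)
}

## ---- SapDatabase methods ----------------------------------------------

#' @rdname SapDatabase-class
#' @export
setMethod("proteinSequences", "SapDatabase", function(x) x@sequences)

#' @rdname SapDatabase-class
#' @export
setMethod("entryInfo", "SapDatabase", function(x) x@entryInfo)

#' @rdname SapDatabase-class
#' @export
setMethod("length", "SapDatabase", function(x) length(x@sequences))

#' @rdname SapDatabase-class
#' @export
setMethod("names", "SapDatabase", function(x) names(x@sequences))

#' @rdname SapDatabase-class
#' @param i index (logical, integer or accession character).
#' @export
setMethod("[", "SapDatabase", function(x, i) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  info <- x@entryInfo[i, , drop = FALSE]
  rownames(info) <- NULL
  new("SapDatabase", sequences = x@sequences[i], entryInfo = info)
})

#' @rdname SapDatabase-class
#' @export
setMethod("targetEntries", "SapDatabase",
          function(x) x[!x@entryInfo$is_decoy])

#' @rdname SapDatabase-class
#' @export
setMethod("decoyEntries", "SapDatabase",
          function(x) x[x@entryInfo$is_decoy])

#' @rdname SapDatabase-class
#' @export
setMethod("sapTable", "SapDatabase", function(x) {
  info <- x@entryInfo
  keep <- info$is_variant & !info$is_decoy
  out <- as.data.frame(info[keep, c("parent_accession", "position",
                                    "ref_aa", "alt_aa", "source_id",
                                    "source_db", "accession")])
  names(out)[1L] <- "protein_accession"
  rownames(out) <- NULL
  out
})

setMethod("show", "SapDatabase", function(object) {
  info <- object@entryInfo
  cat("SapDatabase with", length(object), "entries\n")
  cat(sprintf("  targets: %d (%d wild-type, %d variant) | decoys: %d\n",
              sum(!info$is_decoy),
              sum(!info$is_decoy & !info$is_variant),
              sum(!info$is_decoy & info$is_variant),
              sum(info$is_decoy)))
  nal <- sum(lengths(info$aliases))
  if (nal) cat("  ", nal, " accession(s) merged as exact-sequence aliases\n",
               sep = "")
})
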