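## In-silico tryptic digestion.

#' In-silico tryptic digestion of a protein sequence
#'
#' Cleaves after lysine (K) or arginine (R) except when the following
#' residue is proline (the canonical trypsin rule), and enumerates every
#' fragment with up to \code{missedCleavages} uncut internal sites.
#' Coordinates are 1-based closed residue intervals in the protein.
#'
#' @param sequence single amino-acid string.
#' @param missedCleavages maximum number of internal missed cleavage
#'   sites per peptide (default 2, the usual search-engine setting).
#' @param minLength minimum peptide length retained (default 7).
#' @return data.frame with columns \code{peptide}, \code{start},
#'   \code{end}, \code{missed}, ordered by start then missed cleavages.
#' @examples
#' digestProtein("AAKGGRCC", missedCleavages = 1, minLength = 1)
#' digestProtein("AAKPGG", minLength = 1)   # no cleavage before proline
#' @export
digestProtein <- function(sequence, missedCleavages = 2L, minLength = 7L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence), missedCleavages >= 0L, minLength >= 1L)
  n <- nchar(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sites <- which(ch == "K" | ch == "R")
  sites <- sites[sites < n & ch[pmin(sites + 1L, n)] != "P"]
  bounds <- c(0L, sites, n)
  k <- length(bounds) - 1L          # number of fully-cleaved fragments
  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  for (m in 0:min(missedCleavages, k - 1L)) {
    j <- seq_len(k - m)
    starts <- c(starts, bounds[j] + 1L)
    ends <- c(ends, bounds[j + 1L + m])
    missed <- c(missed, rep.int(m, k - m))
  }
  keep <- which((ends - starts + 1L) >= minLength)
  out <- data.frame(peptide = if (length(keep))
                      substring(sequence, starts[keep], ends[keep])
                    else character(0),
                    start = starts[keep], end = ends[keep],
                    missed = missed[keep], stringsAsFactors = FALSE)
  out <- out[order(out$start, out$missed), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate the theoretically detectable peptides of a SAP
#'
#' Digests a variant protein and keeps the fragments whose span covers
#' the substituted residue; each such peptide carries the alternate
#' amino acid at \code{variant_offset} (1-based within the peptide).
#' A SAP is only detectable by mass spectrometry if at least one such
#' fragment survives the length constraints.
#'
#' @param sequence the variant protein sequence.
#' @param sapPosition 1-based residue index of the substitution.
#' @param missedCleavages,minLength as in [digestProtein()].
#' @return data.frame as from [digestProtein()] plus
#'   \code{variant_offset}.
#' @export
enumerateSapPeptides <- function(sequence, sapPosition,
                                 missedCleavages = 2L, minLength = 7L) {
  stopifnot(sapPosition >= 1L, sapPosition <= nchar(sequence))
  dg <- digestProtein(sequence, missedCleavages, minLength)
  dg <- dg[dg$start <= sapPosition & dg$end >= sapPosition, , drop = FALSE]
  dg$variant_offset <- as.integer(sapPosition) - dg$start + 1L
  rownames(dg) <- NULL
  dg
}
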