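## Independent oracles used across the suite.  Each is a brute-force or
## full-translation re-derivation, deliberately sharing no code with the
## implementation it checks.

## q-values by evaluating the target-decoy FDR at every distinct score
## and taking the minimum over the PSM's own and all lower thresholds.
oracle_qvalues <- function(scores, is_decoy) {
  thr <- sort(unique(scores), decreasing = TRUE)
  fdr <- vapply(thr, function(t) {
    nd <- sum(is_decoy & scores >= t)
    nt <- sum(!is_decoy & scores >= t)
    if (nt == 0L) Inf else nd / nt
  }, numeric(1))
  q <- vapply(seq_along(thr), function(i) min(fdr[i:length(fdr)]), numeric(1))
  pmin(1, q)[match(scores, thr)]
}

## per-base CDS coordinate expansion + full-sequence translation diff;
## independent of the codon arithmetic in the annotator.
oracle_annotate <- function(variant, tx) {
  segs <- methods::slot(tx, "segments")
  gpos <- unlist(lapply(seq_along(segs), function(i)
    seq(IRanges::start(segs)[i], IRanges::end(segs)[i])))
  if (methods::slot(tx, "strand") == "-") gpos <- rev(gpos)
  off <- match(variant$pos, gpos)
  if (is.na(off)) return(list(consequence = "non_coding"))
  flip <- function(b) chartr("ACGT", "TGCA", b)
  refb <- if (methods::slot(tx, "strand") == "-") flip(variant$ref_base) else variant$ref_base
  altb <- if (methods::slot(tx, "strand") == "-") flip(variant$alt_base) else variant$alt_base
  cds <- methods::slot(tx, "cdsSequence")
  if (substr(cds, off, off) != refb)
    return(list(consequence = "reference_mismatch"))
  mut <- cds
  substr(mut, off, off) <- altb
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds), no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(mut), no.init.codon = TRUE))
  if (aa_ref == aa_alt) return(list(consequence = "synonymous"))
  d <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])
  ref_aa <- substr(aa_ref, d, d)
  alt_aa <- substr(aa_alt, d, d)
  if (alt_aa == "*") return(list(consequence = "stop_gain"))
  list(consequence = "missense", position = d, ref_aa = ref_aa,
       alt_aa = alt_aa)
}

## digestion oracle: enumerate all (i, j) substrings bounded by cleavage
## points and count internal sites.
oracle_digest <- function(sequence, missed, min_length) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  sites <- which((ch == "K" | ch == "R") &
                 c(ch[-1], "") != "P" & seq_along(ch) < n)
  bounds <- c(0L, sites, n)
  out <- NULL
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in (i + 1L):length(bounds)) {
      m <- j - i - 1L
      if (m > missed) break
      len <- bounds[j] - bounds[i]
      if (len >= min_length)
        out <- rbind(out, data.frame(
          peptide = substr(sequence, bounds[i] + 1L, bounds[j]),
          start = bounds[i] + 1L, end = bounds[j], missed = m,
          stringsAsFactors = FALSE))
    }
  }
  out
}
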