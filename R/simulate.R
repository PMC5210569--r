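## Seed-deterministic simulator: toy proteomes, coding variants with
## matching transcript models, and scored PSM tables with ground truth.

## Background residue frequencies for toy proteins: roughly the
## composition of a vertebrate proteome, with K+R ~ 11% so tryptic
## digestion yields usable peptides.
.AA_FREQ <- c(A = 0.074, R = 0.053, N = 0.045, D = 0.054, C = 0.018,
              Q = 0.043, E = 0.062, G = 0.070, H = 0.026, I = 0.048,
              L = 0.090, K = 0.058, M = 0.022, F = 0.038, P = 0.057,
              S = 0.081, T = 0.056, W = 0.013, Y = 0.031, V = 0.061)

#' Simulation configuration
#'
#' Defaults define the reference simulation conditions used throughout
#' the package's tests and calibration studies: overlapping Gaussian
#' score distributions (null mean 0, correct mean 3, unit scales), 60%
#' of spectra yielding a correct identification, 5% of correct
#' identifications landing on mutation-carrying peptides, false hits
#' drawn half from decoys (the equal-chance assumption of target-decoy
#' FDR) and tilted towards mutation peptides with probability
#' \code{gammaIntercept + gammaSlope * score}, clamped to \eqn{[0,1]}.
#'
#' @param nProteins number of toy proteins.
#' @param lengthRange uniform bounds of protein length (residues).
#' @param nVariants number of coding variants to plant.
#' @param nSpectra number of simulated spectra (one best PSM each).
#' @param fractionCorrect probability a spectrum's best hit is its true
#'   peptide.
#' @param correctScore,nullScore \code{c(mean, sd)} of the correct-hit
#'   and false-hit score distributions.
#' @param mutationPrevalence fraction of correct identifications on
#'   mutation-carrying peptides.
#' @param gammaSlope,gammaIntercept score tilt of false hits towards
#'   mutation peptides.
#' @param decoyFraction fraction of false hits assigned to decoy
#'   entries.
#' @param chargeStates parent-ion charges sampled for the PSM table.
#' @param seed mandatory integer seed; every stochastic routine sets it.
#' @return named list of class \code{"simConfig"}.
#' @export
simConfig <- function(nProteins = 50L, lengthRange = c(80L, 300L),
                      nVariants = 100L, nSpectra = 10000L,
                      fractionCorrect = 0.6,
                      correctScore = c(mean = 3, sd = 1),
                      nullScore = c(mean = 0, sd = 1),
                      mutationPrevalence = 0.05,
                      gammaSlope = 0.01, gammaIntercept = 0.05,
                      decoyFraction = 0.5,
                      chargeStates = c(2L, 3L, 4L), seed = 1L) {
  cfg <- list(nProteins = as.integer(nProteins),
              lengthRange = as.integer(lengthRange),
              nVariants = as.integer(nVariants),
              nSpectra = as.integer(nSpectra),
              fractionCorrect = fractionCorrect,
              correctScore = correctScore, nullScore = nullScore,
              mutationPrevalence = mutationPrevalence,
              gammaSlope = gammaSlope, gammaIntercept = gammaIntercept,
              decoyFraction = decoyFraction,
              chargeStates = as.integer(chargeStates),
              seed = as.integer(seed))
  stopifnot(cfg$nProteins >= 1L, length(cfg$lengthRange) == 2L,
            cfg$lengthRange[1L] >= 10L,
            cfg$lengthRange[2L] >= cfg$lengthRange[1L],
            cfg$fractionCorrect >= 0, cfg$fractionCorrect <= 1,
            cfg$mutationPrevalence >= 0, cfg$mutationPrevalence <= 1,
            cfg$decoyFraction >= 0, cfg$decoyFraction <= 1,
            cfg$correctScore[["sd"]] > 0, cfg$nullScore[["sd"]] > 0,
            length(cfg$seed) == 1L, !is.na(cfg$seed))
  class(cfg) <- "simConfig"
  cfg
}

#' Generate a toy wild-type proteome
#'
#' Random proteins over the 20-letter alphabet with vertebrate-like
#' residue frequencies (K+R around 11%, so tryptic digestion of any
#' protein yields peptides of usable length) and uniform lengths.
#' Identical config and seed give byte-identical output.
#'
#' @param config a [simConfig()].
#' @return [Biostrings::AAStringSet] named \code{SIMP0001} ...
#' @export
makeToyProteome <- function(config = simConfig()) {
  set.seed(config$seed)
  lens <- sample.int(config$lengthRange[2L] - config$lengthRange[1L] + 1L,
                     config$nProteins, replace = TRUE) +
    config$lengthRange[1L] - 1L
  seqs <- vapply(lens, function(n)
    paste(sample(names(.AA_FREQ), n, replace = TRUE, prob = .AA_FREQ),
          collapse = ""), "")
  AAStringSet(setNames(seqs, sprintf("SIMP%04d", seq_along(seqs))))
}

## All single-nucleotide codon changes, precomputed once: for each
## (codon, position, alternative base) the reference and mutated
## residue and the consequence class.
.codon_change_table <- function() {
  codons <- names(GENETIC_CODE)
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(codon = codons, cpos = 1:3, alt = bases,
                      stringsAsFactors = FALSE)
  grid$ref <- substr(grid$codon, grid$cpos, grid$cpos)
  grid <- grid[grid$ref != grid$alt, , drop = FALSE]
  mut <- grid$codon
  substr(mut, grid$cpos, grid$cpos) <- grid$alt
  grid$mcodon <- mut
  grid$ref_aa <- unname(GENETIC_CODE[grid$codon])
  grid$alt_aa <- unname(GENETIC_CODE[grid$mcodon])
  grid$consequence <- ifelse(grid$ref_aa == "*", "stop_codon",
                      ifelse(grid$alt_aa == "*", "stop_gain",
                      ifelse(grid$ref_aa == grid$alt_aa, "synonymous",
                             "missense")))
  grid
}

## reverse complement of a nucleotide string (plain character)
.revcomp <- function(s)
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                                     collapse = ""), "", USE.NAMES = FALSE))

## random CDS encoding a protein (synonymous codon drawn per residue)
.random_cds <- function(protein, codons_by_aa) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1L]]
  paste(vapply(ch, function(a) {
    cs <- codons_by_aa[[a]]
    cs[sample.int(length(cs), 1L)]
  }, "", USE.NAMES = FALSE), collapse = "")
}

## random transcript model for a protein: 1-3 CDS segments on a
## dedicated chromosome, either strand
.random_transcript <- function(accession, protein, chrom, codons_by_aa) {
  cds <- .random_cds(protein, codons_by_aa)
  L <- nchar(cds)
  strand <- sample(c("+", "-"), 1L)
  nseg <- sample.int(min(3L, L - 1L), 1L)
  cuts <- if (nseg > 1L) sort(sample.int(L - 1L, nseg - 1L)) else integer(0)
  lens <- diff(c(0L, cuts, L))
  ## ascending genomic segments; on '-' the transcript reads them in
  ## descending genomic order, so segment widths follow the reversed
  ## piece lengths
  seg_lens <- if (strand == "+") lens else rev(lens)
  gaps <- sample.int(100L, nseg) + 9L
  starts <- integer(nseg); pos <- sample.int(1000L, 1L)
  for (j in seq_len(nseg)) {
    starts[j] <- pos
    pos <- pos + seg_lens[j] + gaps[j]
  }
  segs <- IRanges(start = starts, width = seg_lens)
  transcriptModel(paste0("TX_", accession), accession, chrom, strand,
                  segs, cds)
}

## CDS offset (1-based, transcript orientation) -> genomic position
.genomic_pos <- function(tx, off) {
  w <- width(tx@segments); st <- start(tx@segments); en <- end(tx@segments)
  if (tx@strand == "+") {
    cw <- cumsum(w)
    i <- which(off <= cw)[1L]
    before <- if (i > 1L) cw[i - 1L] else 0L
    st[i] + (off - before) - 1L
  } else {
    wrev <- rev(w)                      # transcript order
    cw <- cumsum(wrev)
    j <- which(off <= cw)[1L]           # j-th segment in transcript order
    before <- if (j > 1L) cw[j - 1L] else 0L
    i <- length(w) - j + 1L             # genomic index
    en[i] - (off - before) + 1L
  }
}

#' Plant coding variants with matching transcript models
#'
#' Samples random residues of the proteome and, for each, a
#' single-nucleotide codon change of the requested consequence class,
#' then emits the consistent triple (genomic variant record, transcript
#' model, CDS sequence) that [annotateMissense()] must map back to the
#' same amino-acid substitution — a built-in round trip of the
#' annotator.  Transcripts (one per protein, random strand, 1-3 CDS
#' segments) are shared by all variants of a protein.
#'
#' @param proteome [Biostrings::AAStringSet] (e.g. from
#'   [makeToyProteome()]).
#' @param config a [simConfig()]; \code{nVariants} and \code{seed} are
#'   used.
#' @param consequence \code{"missense"} (default) to plant only
#'   missense changes, or \code{"any"} to sample uniformly from all
#'   single-nucleotide codon changes (missense, synonymous, stop-gain).
#' @return list with \code{saps} (SAP records for the missense
#'   variants), \code{variants} (genomic records with a
#'   \code{truth_consequence} column), \code{transcripts} (named list
#'   of [TranscriptModel-class]).
#' @export
makeVariants <- function(proteome, config = simConfig(),
                         consequence = c("missense", "any")) {
  consequence <- match.arg(consequence)
  set.seed(config$seed + 1L)
  n <- config$nVariants
  gc <- GENETIC_CODE
  codons_by_aa <- split(names(gc), unname(gc))
  changes <- .codon_change_table()
  changes <- changes[changes$consequence !=  "stop_codon", , drop = FALSE]
  if (consequence == "missense")
    changes <- changes[changes$consequence == "missense", , drop = FALSE]
  accs <- names(proteome)
  pick_prot <- if (n) sample(seq_along(accs), n, replace = TRUE) else integer(0)
  transcripts <- list()
  saps <- vector("list", n); variants <- vector("list", n)
  for (i in seq_len(n)) {
    acc <- accs[pick_prot[i]]
    prot <- as.character(proteome[[acc]])
    if (is.null(transcripts[[paste0("TX_", acc)]])) {
      tx <- .random_transcript(acc, prot, paste0("chrS", pick_prot[i]),
                               codons_by_aa)
      transcripts[[tx@transcriptId]] <- tx
    }
    tx <- transcripts[[paste0("TX_", acc)]]
    pos_aa <- sample.int(nchar(prot), 1L)
    codon <- substr(tx@cdsSequence, 3L * pos_aa - 2L, 3L * pos_aa)
    cand <- changes[changes$codon == codon, , drop = FALSE]
    if (!nrow(cand)) next    # e.g. only stop-gain neighbours requested away
    ch <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
    off <- 3L * (pos_aa - 1L) + ch$cpos
    gpos <- .genomic_pos(tx, off)
    minus <- tx@strand == "-"
    ref_g <- if (minus) .COMPLEMENT[[ch$ref]] else ch$ref
    alt_g <- if (minus) .COMPLEMENT[[ch$alt]] else ch$alt
    sid <- sprintf("rs%06d", i)
    variants[[i]] <- data.frame(chrom = tx@chrom, pos = gpos,
                                ref_base = ref_g, alt_base = alt_g,
                                source_id = sid, source_db = "simulated",
                                transcript_id = tx@transcriptId,
                                truth_consequence = ch$consequence,
                                stringsAsFactors = FALSE)
    if (ch$consequence == "missense")
      saps[[i]] <- data.frame(protein_accession = acc, position = pos_aa,
                              ref_aa = ch$ref_aa, alt_aa = ch$alt_aa,
                              source_id = sid, source_db = "simulated",
                              stringsAsFactors = FALSE)
  }
  sap_tab <- do.call(rbind, saps[!vapply(saps, is.null, logical(1L))])
  if (is.null(sap_tab)) sap_tab <- .empty_sap_table()
  var_tab <- do.call(rbind, variants[!vapply(variants, is.null, logical(1L))])
  if (is.null(var_tab))
    var_tab <- data.frame(chrom = character(), pos = integer(),
                          ref_base = character(), alt_base = character(),
                          source_id = character(), source_db = character(),
                          transcript_id = character(),
                          truth_consequence = character(),
                          stringsAsFactors = FALSE)
  rownames(sap_tab) <- NULL; rownames(var_tab) <- NULL
  list(saps = sap_tab, variants = var_tab, transcripts = transcripts)
}

## Candidate peptide pools of a database, split by target/decoy and
## mutation status.  Mutation targets are SAP-covering peptides of
## variant entries; decoy "mutation" peptides come from decoys of
## variant entries (mirroring accession-based labelling).
#' Candidate peptide pools of a SAP database
#'
#' Digests every database entry and splits the resulting peptides into
#' the four pools used by [simulatePsms()]: target/decoy crossed with
#' mutation/non-mutation.  Mutation target peptides are the
#' SAP-covering fragments of variant entries ([enumerateSapPeptides()]);
#' decoy peptides count as mutation-carrying when they derive from the
#' decoy of a variant entry.
#'
#' @param database a [SapDatabase-class].
#' @param missedCleavages,minLength digestion parameters.
#' @return list of four data.frames (\code{target_mut},
#'   \code{target_wt}, \code{decoy_mut}, \code{decoy_wt}) with columns
#'   \code{peptide}, \code{accession}.
#' @export
peptidePools <- function(database, missedCleavages = 2L, minLength = 7L) {
  info <- entryInfo(database)
  seqs <- as.character(proteinSequences(database))
  pool <- function(idx, sap_only) {
    rows <- lapply(which(idx), function(i) {
      dg <- if (sap_only)
        enumerateSapPeptides(seqs[i], info$position[i],
                             missedCleavages, minLength)
      else digestProtein(seqs[i], missedCleavages, minLength)
      if (!nrow(dg)) return(NULL)
      data.frame(peptide = dg$peptide, accession = info$accession[i],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
    if (is.null(out)) data.frame(peptide = character(),
                                 accession = character(),
                                 stringsAsFactors = FALSE)
    else out
  }
  list(target_mut = pool(info$is_variant & !info$is_decoy, TRUE),
       target_wt = pool(!info$is_variant & !info$is_decoy, FALSE),
       decoy_mut = pool(info$is_variant & info$is_decoy, FALSE),
       decoy_wt = pool(!info$is_variant & info$is_decoy, FALSE))
}

#' Simulate a scored PSM table with ground-truth labels
#'
#' One best PSM per simulated spectrum.  With probability
#' \code{fractionCorrect} the spectrum is correctly identified: its
#' peptide is drawn from the target pools (mutation-carrying with
#' probability \code{mutationPrevalence}) and its score from the
#' correct-hit distribution.  Otherwise the identification is false:
#' the score is drawn from the null distribution, the entry is a decoy
#' with probability \code{decoyFraction}, and the peptide lands on a
#' mutation-carrying pool with probability
#' \code{clamp(gammaIntercept + gammaSlope * score, 0, 1)} — the
#' score-dependent tilt whose coefficients [fitGamma()] estimates.
#'
#' Ground truth travels with the table: \code{is_false} (the
#' identification is wrong) and \code{is_mutation} (the matched peptide
#' carries a SAP), enabling exact false-discovery-proportion
#' computation at any threshold.
#'
#' @param database a [SapDatabase-class] with targets and decoys.
#' @param config a [simConfig()].
#' @param pools optional precomputed [peptidePools()] (e.g. when
#'   simulating many replicates from one database).
#' @return data.frame with columns \code{spectrum_id}, \code{peptide},
#'   \code{score}, \code{charge}, \code{proteins}, \code{is_decoy},
#'   \code{is_mutation}, \code{is_false}.
#' @export
simulatePsms <- function(database, config = simConfig(), pools = NULL) {
  if (is.null(pools)) pools <- peptidePools(database)
  stopifnot(nrow(pools$target_mut) > 0L, nrow(pools$target_wt) > 0L,
            nrow(pools$decoy_mut) > 0L, nrow(pools$decoy_wt) > 0L)
  set.seed(config$seed + 2L)
  n <- config$nSpectra
  correct <- runif(n) < config$fractionCorrect
  score <- ifelse(correct,
                  rnorm(n, config$correctScore[["mean"]],
                        config$correctScore[["sd"]]),
                  rnorm(n, config$nullScore[["mean"]],
                        config$nullScore[["sd"]]))
  is_decoy <- !correct & runif(n) < config$decoyFraction
  pmut <- pmin(1, pmax(0, config$gammaIntercept + config$gammaSlope * score))
  is_mut <- ifelse(correct, runif(n) < config$mutationPrevalence,
                   runif(n) < pmut)
  pool_of <- function(dec, mut)
    if (dec) { if (mut) pools$decoy_mut else pools$decoy_wt }
    else     { if (mut) pools$target_mut else pools$target_wt }
  key <- paste0(ifelse(is_decoy, "D", "T"), ifelse(is_mut, "M", "W"))
  peptide <- character(n); proteins <- character(n)
  for (k in unique(key)) {
    idx <- which(key == k)
    p <- pool_of(substr(k, 1L, 1L) == "D", substr(k, 2L, 2L) == "M")
    ridx <- sample.int(nrow(p), length(idx), replace = TRUE)
    peptide[idx] <- p$peptide[ridx]
    proteins[idx] <- p$accession[ridx]
  }
  data.frame(spectrum_id = sprintf("SPC%07d", seq_len(n)),
             peptide = peptide, score = score,
             charge = sample(config$chargeStates, n, replace = TRUE),
             proteins = proteins, is_decoy = is_decoy,
             is_mutation = is_mut, is_false = !correct,
             stringsAsFactors = FALSE)
}
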