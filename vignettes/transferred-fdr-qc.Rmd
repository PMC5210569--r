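---
title: "Variant peptide detection with sapQC: database construction and the transferred FDR"
author: "sapQC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant peptide detection with sapQC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sapQC)
```

## The problem

Shotgun proteomics identifies peptides by matching MS/MS spectra against a
protein sequence database. A single amino-acid polymorphism (SAP) — the
protein-level consequence of a non-synonymous SNV — is invisible to this
search unless the substituted sequence is present in the database. The
remedy is a customized database in which each annotated variant contributes
a protein copy with the reference residue replaced by the alternative one.
This fixes the visibility problem but creates a statistical one: variant
entries inflate the search space with sequences that differ from true
proteins by a single residue, so the mutation-carrying subset of
identifications has a much worse error profile than the identification list
as a whole, and a global FDR threshold understates the false discovery rate
among SAP calls. sapQC implements both halves: the database construction
and the subgroup-aware quality-control cascade.

## Database construction

`annotateMissense()` maps a genomic SNV onto its codon using a transcript
model (CDS segments in ascending genomic order plus the CDS sequence in
transcript orientation). On minus-strand transcripts both alleles are
complemented and the transcript reads the segments back-to-front; the codon
index is `ceiling(offset / 3)`. Only single-nucleotide substitutions are
annotated; synonymous changes and stop gains are counted and skipped, since
a SAP is by definition a single-residue substitution, and indels or
multi-nucleotide variants are rejected with a typed reason. Positions are
1-based throughout (genomic, CDS, and protein), matching VCF and the
`A673V` protein notation.

`applySap()` performs the substitution and derives the accession
`<parent>|SAP|<ref><pos><alt>|<source_id>`, so provenance survives FASTA
round trips. `mergeAndDedupe()` removes exact duplicate sequences — the
first entry in input order survives and records the merged accessions as
aliases; wild-type entries are placed before variants so they win ties.
Deduplication treats I and L as distinct residues: folding isobaric
residues is a detection-time concern and is available as an explicit option
in the collision filter instead. `buildDecoys()` appends one whole-sequence
reversal per target with a fixed `DECOY_` prefix, preserving length and
composition. Digestion (`digestProtein()`) uses the canonical trypsin rule
— cleave after K or R, never before P — with up to 2 missed cleavages and a
7-residue minimum by default.

## Global and subgroup FDR

`computeQvalues()` ranks PSMs by score and estimates, at each threshold
*s*, `FDR(s) = #decoys(score >= s) / #targets(score >= s)` (plain ratio; a
+1 pseudo-count is available as a conservative option). The q-value is the
running minimum of this ratio over the PSM's own and all lower thresholds;
tied scores share a threshold, and a PSM counts itself at its own score.
The default retention rule is q <= 0.01.

The subgroup problem: let *F* be the event that an identification is false
and *I~k~* that it lands on a mutation-carrying peptide. The subgroup FDR
of mutation identifications above a threshold,
`FDR_k(x) = P(F | I_k, X > x)`, can be rewritten by Bayes' rule as

    FDR_k(x) = N(x) / N_k(x) * gamma_k(x) * FDR(x)

where `N(x)` and `N_k(x)` count all and mutation-carrying target
identifications above `x`, and `gamma_k(x)` is the probability that a false
identification above `x` carries a mutation. Because it is transferred
from the (well-estimated) global FDR rather than computed from the sparse
mutation subgroup alone, this estimate remains stable even when only a few
hundred mutation PSMs exist. `gamma_k` is modelled as a straight line
`a*x + b` in the score.

### Estimating the line

The false-identification population is not observable directly; decoy PSMs
are its standard stand-in, so `fitGamma()` estimates the line from the
decoy population and the mutation labels of decoy entries (a decoy counts
as mutation-carrying when it derives from a variant entry). Two estimators
are provided:

* **binned** (default): decoy scores are cut into 20 quantile cells
  (cells under 10 observations are merged with a neighbour), and the
  mutation fraction per cell is regressed by OLS on the mean decoy score of
  the cell. Because each cell fraction estimates the local mutation
  probability at its mean score, this recovers the underlying linear score
  dependence without attenuation.
* **cumulative**: the mutation fraction among all decoys *above* each grid
  threshold, regressed on the threshold. This is the running-tail form in
  which `gamma_k` enters the FDR formula, but tail averages integrate over
  the score distribution above each threshold and therefore flatten the
  slope (for a Gaussian score null, roughly by half). The cumulative mode
  is kept for diagnostics; the binned mode is used to estimate the line.

Evaluation always clamps `a*x + b` to [0, 1]. When the decoy data are too
sparse for a slope (fewer than two usable cells, or a degenerate score
spread), the fit falls back to a constant — slope 0 and the pooled decoy
mutation fraction — with a warning, which degrades the transferred FDR
gracefully to a scaled global FDR.

Evaluating the fitted line at the threshold `x` slightly understates the
tail-average `gamma_k` when the slope is positive (the mean score above
`x` exceeds `x`). At the 1% working point the resulting error in `FDR_k`
is a few percent relative, well inside the calibration band the tests
enforce; the formula is kept in its published closed form.

`groupQvalues()` evaluates the transferred FDR at every distinct
mutation-target score and monotonizes over descending score into a
subgroup q-value, so thresholding behaves like ordinary q-value filtering.
The subgroup cutoff defaults to 0.01, configurable in `sapConfig()`.

## The cascade

`runCascade()` applies, in order: global FDR filter (q <= 0.01) — peptide
length filter (strictly longer than 9 residues; shorter peptides map too
promiscuously to support a single-residue claim) — SAP-site mapping
(a peptide is a SAP peptide only if an exact occurrence in a variant entry
covers the substituted position) — wild-type collision exclusion (the
variant peptide must not occur verbatim anywhere in the wild-type proteome;
optional I=L folding for the isobaric pair) — the group-FDR filter on the
mutation subgroup — the PTM collision split — and protein reassembly.

PTM collisions are SAP calls indistinguishable from a post-translational
modification of the wild-type peptide: deamidation converts N to D and Q
to E with near-SAP mass shifts, so a SAP peptide whose *wild-type
counterpart* appears in a supplied PTM peptide set is moved to a separate
output rather than deleted — it is evidence of something, just not
unambiguous evidence of a variant. A built-in rule table additionally
flags (without excluding) N->D and Q->E substitutions. Related,
`flagIsobaric()` marks substitutions whose residue-mass difference falls
inside an instrument tolerance (L->I is exactly 0, K->Q is ~0.036 Da).

Every stage reports distinct peptides, proteins and spectra retained, and
every candidate peptide ends in exactly one terminal bucket (retained,
too-short, non-SAP, unmapped, wild-type collision, failed group FDR, PTM
collision), so bucket counts reconcile with the post-filter universe.
Protein reassembly groups retained peptides by variant accession; the
default support threshold is a single peptide (configurable), since the
cascade has already vetted each peptide individually.

Two decisions the workflow's description leaves open are resolved as
follows: the group FDR is computed after SAP mapping, on the
mapping-derived mutation subgroup, because that is the population the
subgroup estimand refers to; and the transferred FDR is monotonized into a
q-analogue before thresholding, so retention is monotone in score.
Peptide-level q-values are used throughout; no separate protein-level FDR
is computed.

## The simulator

`makeToyProteome()`, `makeVariants()` and `simulatePsms()` generate the
inputs the cascade and its statistics need, with known ground truth. Toy
proteins use vertebrate-like residue frequencies (K+R about 11%, so tryptic
digests are non-trivial); variants are planted as single-nucleotide codon
changes with consistent transcript models on both strands, which makes the
annotator testable by round trip. PSM scores follow two Gaussians — null
N(0, 1), correct N(3, 1) — overlapping enough to make thresholding
non-trivial; 60% of spectra are correctly identified; false hits fall on
decoys with probability 0.5 (the equal-chance assumption under target-decoy
estimation) and on mutation-carrying peptides with probability
`0.05 + 0.01 * score`, the linear tilt whose coefficients the gamma fit
must recover; correct identifications land on mutation peptides at 5%
prevalence. All generators are deterministic given the seed.

What the simulator does not model: spectra (only score-level PSMs),
score distributions with heavy tails or charge dependence, homologous
near-duplicate proteins, RNA editing, sequencing error, or contamination.
Passing calibration tests on these simulations therefore demonstrates the
statistical machinery is correct under its stated assumptions, not that
any particular real dataset meets those assumptions.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` use: 1000 random PSM lists of
20–79 PSMs for exact q-value oracle agreement; 20 replicates of 20,000
spectra (about 10^4 false hits each) for gamma-line recovery, judged
against two standard errors of the replicate mean; 20 replicates of 50,000
PSMs at 5% mutation prevalence for subgroup calibration (mean realized FDP
at group q <= 0.01, and the gap between estimate and realized FDP); 10^4
annotator round trips over 200 transcripts on both strands; and a planted
four-peptide cascade fixture with one known outcome per bucket.

## Limitations

* `gamma_k` estimation assumes decoys model the false population and that
  variant-derived decoys inherit the mutation label meaningfully; both are
  inherited from the target-decoy framework rather than proven.
* The linear form of `gamma_k(x)` is an empirical approximation; data with
  a strongly non-linear mutation tilt would need a richer model. The
  per-cell observed fractions stored in the `GammaFit` object make lack of
  fit visible.
* Exact-substring mapping does not consider modified residues or
  semi-tryptic peptides.
* Transcript isoform mapping, genome-build lift-over, splice-site and
  frameshift consequences are out of scope; the annotator handles clean
  CDS models only.
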