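Package: sapQC
Title: Variant Protein Database Construction and Group-FDR Quality
    Control for Single Amino-Acid Polymorphism Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds customized protein sequence databases that carry
    single amino-acid polymorphisms (SAPs) derived from non-synonymous
    single-nucleotide variants, and runs a quality-control cascade over
    search-engine peptide-spectrum matches: target-decoy q-values for
    global false discovery rate control, peptide length and SAP-site
    filters, wild-type and PTM collision exclusion, and a subgroup
    ("transferred") FDR for mutation-carrying peptides based on a linear
    model of the mutation fraction among false identifications.
    Includes in-silico tryptic digestion, missense annotation of coding
    SNVs, decoy database generation, and a seed-deterministic simulator
    of proteomes, variants and scored PSM tables with ground-truth
    labels for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
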