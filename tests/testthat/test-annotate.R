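test_that("codon substitution is classified and mapped correctly", {
  tx <- transcriptModel("T1", "P1", "chr1", "+", cbind(101, 109),
                        "ATGGCCAAA")   # M A K
  # GCC with middle C->T gives GTC: Ala -> Val
  sap <- annotateMissense(list(chrom = "chr1", pos = 105, ref_base = "C",
                               alt_base = "T", source_id = "rs1"), tx)
  expect_identical(nrow(sap), 1L)
  expect_identical(sap$ref_aa, "A")
  expect_identical(sap$alt_aa, "V")
  expect_identical(sap$position, 2L)
  # GCC with third base C->A gives GCA: still Ala, no SAP record
  syn <- annotateMissense(list(chrom = "chr1", pos = 106, ref_base = "C",
                               alt_base = "A", source_id = "rs2"), tx)
  expect_identical(nrow(syn), 0L)
  expect_identical(attr(syn, "consequence"), "synonymous")
  # AAA -> TAA is a stop gain, skipped rather than reported as a SAP
  sg <- annotateMissense(list(chrom = "chr1", pos = 107, ref_base = "A",
                              alt_base = "T", source_id = "rs3"), tx)
  expect_identical(nrow(sg), 0L)
  expect_identical(attr(sg, "consequence"), "stop_gain")
})

test_that("errors are signalled as classed conditions", {
  tx <- transcriptModel("T1", "P1", "chr1", "+", cbind(101, 109),
                        "ATGGCCAAA")
  expect_error(
    annotateMissense(list(chrom = "chr1", pos = 50, ref_base = "C",
                          alt_base = "T", source_id = "x"), tx),
    class = "sapQC_non_coding")
  expect_error(
    annotateMissense(list(chrom = "chr1", pos = 105, ref_base = "G",
                          alt_base = "T", source_id = "x"), tx),
    class = "sapQC_reference_mismatch")
  expect_error(
    annotateMissense(list(chrom = "chr1", pos = 105, ref_base = "CC",
                          alt_base = "T", source_id = "x"), tx),
    class = "sapQC_not_snv")
})

test_that("minus-strand variants are reverse-complemented before lookup", {
  # same CDS, but carried on the minus strand over two segments:
  # transcript order reads the genomic segments back-to-front
  tx <- transcriptModel("T2", "P2", "chr2", "-",
                        rbind(c(201, 203), c(301, 306)),
                        "ATGGCCAAA")
  # CDS offset 5 (the middle C of GCC) sits in transcript piece 1
  # (genomic segment 2, read right-to-left): genomic pos 302, base G
  sap <- annotateMissense(list(chrom = "chr2", pos = 302, ref_base = "G",
                               alt_base = "A", source_id = "rs4"), tx)
  expect_identical(sap$ref_aa, "A")
  expect_identical(sap$alt_aa, "V")
  expect_identical(sap$position, 2L)
})

test_that("a variant producing Ala->Val at residue 673 renders as A673V", {
  prot <- paste(rep("A", 700), collapse = "")
  sap <- data.frame(protein_accession = "APP", position = 673L,
                    ref_aa = "A", alt_aa = "V", source_id = "rs63750264",
                    stringsAsFactors = FALSE)
  expect_identical(sapNotation(sap$ref_aa, sap$position, sap$alt_aa),
                   "A673V")
  ent <- applySap(c(APP = prot), sap)
  expect_identical(substr(unname(ent), 673, 673), "V")
  expect_identical(names(ent), "APP|SAP|A673V|rs63750264")
})

test_that("annotation agrees with a full-translation diff oracle", {
  cfg <- simConfig(nProteins = 15L, nVariants = 300L, seed = 23L)
  proteome <- makeToyProteome(cfg)
  gen <- makeVariants(proteome, cfg, consequence = "any")
  ann <- annotateVariants(gen$variants, gen$transcripts, proteome)
  expect_identical(ann$consequence, gen$variants$truth_consequence)
  for (i in seq_len(nrow(gen$variants))) {
    v <- lapply(gen$variants, `[`, i)
    want <- oracle_annotate(v, gen$transcripts[[v$transcript_id]])
    expect_identical(ann$consequence[i], want$consequence)
    if (want$consequence == "missense") {
      got <- ann$saps[ann$saps$source_id == v$source_id, ]
      expect_identical(got$position, want$position)
      expect_identical(got$ref_aa, want$ref_aa)
      expect_identical(got$alt_aa, want$alt_aa)
    }
  }
})

test_that("simulated variants round-trip through the annotator", {
  cfg <- simConfig(nProteins = 10L, nVariants = 150L, seed = 5L)
  proteome <- makeToyProteome(cfg)
  gen <- makeVariants(proteome, cfg)   # missense only
  strands <- vapply(gen$transcripts, function(t) methods::slot(t, "strand"), "")
  expect_setequal(unique(strands), c("+", "-"))
  ann <- annotateVariants(gen$variants, gen$transcripts, proteome)
  expect_identical(nrow(ann$saps), nrow(gen$saps))
  a <- ann$saps[order(ann$saps$source_id),
                c("protein_accession", "position", "ref_aa", "alt_aa")]
  b <- gen$saps[order(gen$saps$source_id),
                c("protein_accession", "position", "ref_aa", "alt_aa")]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})
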