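test_that("applySap substitutes exactly one residue and is invertible", {
  ent <- applySap(c(P1 = "MKT"), list(position = 2, ref_aa = "K",
                                      alt_aa = "R", source_id = "v1"))
  expect_identical(unname(ent), "MRT")
  expect_identical(names(ent), "P1|SAP|K2R|v1")
  # inverse substitution restores the parent
  back <- applySap(setNames(unname(ent), "P1"),
                   list(position = 2, ref_aa = "R", alt_aa = "K",
                        source_id = "v1"))
  expect_identical(unname(back), "MKT")
  # stale annotation: warn and drop
  expect_warning(
    out <- applySap(c(P1 = "MKT"), list(position = 2, ref_aa = "Q",
                                        alt_aa = "R", source_id = "v1")),
    "stale")
  expect_null(out)
})

test_that("deduplication keeps the first entry and records aliases", {
  out <- mergeAndDedupe(c(P1 = "MKT", P2 = "MKT", P3 = "AAA"))
  expect_identical(names(out), c("P1", "P3"))
  expect_identical(as.list(S4Vectors::mcols(out)$aliases)[[1]], "P2")
  # all-distinct input passes through unchanged
  distinct <- c(A = "MK", B = "MR", C = "ML")
  expect_identical(as.character(mergeAndDedupe(distinct)), distinct)
})

test_that("deduplication is idempotent and conserves accession count", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    pool <- c("MKT", "AAA", "GGR", "MKAR", "TTT")
    seqs <- setNames(sample(pool, n, replace = TRUE),
                     paste0("E", seq_len(n)))
    once <- mergeAndDedupe(seqs)
    twice <- mergeAndDedupe(once)
    expect_identical(as.character(once), as.character(twice))
    expect_identical(as.list(S4Vectors::mcols(once)$aliases),
                     as.list(S4Vectors::mcols(twice)$aliases))
    expect_identical(length(once) + sum(lengths(S4Vectors::mcols(once)$aliases)),
                     length(seqs))
  }
})

test_that("decoys are whole-sequence reversals with preserved lengths", {
  targets <- c(P1 = "MKTR", P2 = "AAGGC")
  dec <- buildDecoys(targets)
  expect_identical(as.character(dec),
                   c(DECOY_P1 = "RTKM", DECOY_P2 = "CGGAA"))
  expect_identical(unname(Biostrings::width(dec)), nchar(unname(targets)))
  # reversal is an involution
  again <- buildDecoys(setNames(as.character(dec), names(targets)))
  expect_identical(unname(as.character(again)), unname(targets))
})

test_that("buildSapDatabase assembles variants, dedupe and decoys", {
  proteome <- c(P1 = "MVVVVAVVVVKGGG", P2 = "MWWWWNWWWWKCCC")
  saps <- data.frame(protein_accession = c("P1", "P2"),
                     position = c(6L, 6L), ref_aa = c("A", "N"),
                     alt_aa = c("G", "S"), source_id = c("s1", "s2"),
                     stringsAsFactors = FALSE)
  db <- buildSapDatabase(proteome, saps)
  info <- entryInfo(db)
  expect_identical(length(db), 8L)           # 2 wt + 2 var, doubled by decoys
  expect_identical(sum(info$is_decoy), 4L)
  # every variant entry differs from its parent at exactly the SAP site
  seqs <- as.character(proteinSequences(db))
  for (i in which(info$is_variant & !info$is_decoy)) {
    parent <- unname(seqs[info$parent_accession[i]])
    v <- unname(seqs[i])
    diffs <- which(strsplit(parent, "")[[1]] != strsplit(v, "")[[1]])
    expect_identical(diffs, info$position[i])
    expect_identical(substr(v, diffs, diffs), info$alt_aa[i])
  }
  # sapTable carries the substitution records
  st <- sapTable(db)
  expect_setequal(st$source_id, c("s1", "s2"))
  # decoy entries mirror target count and length multiset
  expect_identical(sort(Biostrings::width(proteinSequences(targetEntries(db)))),
                   sort(Biostrings::width(proteinSequences(decoyEntries(db)))))
})

test_that("variant sequences duplicating a wild-type entry are merged", {
  # P2 equals P1 with A6G already; the planted variant of P1 collides
  proteome <- c(P1 = "MVVVVAVVVVKGGG", P2 = "MVVVVGVVVVKGGG")
  saps <- data.frame(protein_accession = "P1", position = 6L,
                     ref_aa = "A", alt_aa = "G", source_id = "s1",
                     stringsAsFactors = FALSE)
  db <- buildSapDatabase(proteome, saps)
  info <- entryInfo(db)
  expect_identical(sum(!info$is_decoy), 2L)  # wild-type entry survives
  expect_true("P1|SAP|A6G|s1" %in%
              unlist(as.list(info$aliases[info$accession == "P2"])))
})

test_that("isobaric substitutions are flagged at the right tolerances", {
  expect_true(flagIsobaric("I", "L", toleranceDa = 0))
  expect_true(flagIsobaric("K", "Q", toleranceDa = 0.05))
  expect_false(flagIsobaric("K", "Q", toleranceDa = 0.01))
  expect_false(flagIsobaric("A", "V", toleranceDa = 0.05))
  # the K/Q residue-mass gap is the documented ~0.036 Da
  m <- residueMasses()
  expect_lt(abs(abs(m[["K"]] - m[["Q"]]) - 0.036), 0.001)
})
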