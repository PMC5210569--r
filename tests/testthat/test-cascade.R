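test_that("global FDR filter is boundary-inclusive and drops decoys", {
  p <- data.frame(score = c(5, 4, 3, 2), is_decoy = c(FALSE, FALSE, FALSE, TRUE),
                  q_value = c(0.005, 0.01, 0.011, 0.002))
  out <- filterGlobalFdr(p)
  expect_identical(out$q_value, c(0.005, 0.01))
  expect_identical(nrow(filterGlobalFdr(p[0, ])), 0L)
})

test_that("length filter keeps peptides strictly longer than 9 residues", {
  p <- data.frame(peptide = c(strrep("A", 9), strrep("A", 10)))
  expect_identical(filterLength(p)$peptide, strrep("A", 10))
  short <- data.frame(peptide = c("AAA", "PEPTIDE"))
  expect_identical(nrow(filterLength(short)), 0L)
  set.seed(8)
  lens <- sample(5:20, 200, replace = TRUE)
  tab <- data.frame(peptide = vapply(lens, strrep, "", x = "K"))
  expect_identical(nrow(filterLength(tab)), sum(lens > 9))
})

test_that("SAP mapping requires site coverage with the variant residue", {
  fx <- cascade_fixture()
  psms <- data.frame(spectrum_id = c("a", "b", "c"),
                     peptide = c("MVVVVGVVVVK", "GGG", "ELVISLIVESK"),
                     score = c(9, 8, 7), is_decoy = FALSE,
                     proteins = "x", q_value = 0)
  map <- mapSapPeptides(psms, fx$db)
  # covering peptide with the alternate residue -> SAP peptide
  expect_identical(map$peptide, "MVVVVGVVVVK")
  expect_identical(map$variant_offset, 6L)
  expect_identical(map$wildtype_peptide, "MVVVVAVVVVK")
  # inside a variant protein but not overlapping the SAP -> non-SAP
  expect_identical(attr(map, "non_sap"), "GGG")
  # matching nothing in the database -> unmapped diagnostics
  expect_identical(attr(map, "unmapped"), "ELVISLIVESK")
})

test_that("one peptide shared by two variant proteins gives one row", {
  proteome <- c(PX1 = "MHHHHAHHHHKLLL", PX2 = "GGGKMHHHHAHHHHKPPPR")
  saps <- data.frame(protein_accession = c("PX1", "PX2"),
                     position = c(6L, 10L), ref_aa = "A", alt_aa = "G",
                     source_id = c("u1", "u2"), stringsAsFactors = FALSE)
  db <- buildSapDatabase(proteome, saps)
  psms <- data.frame(spectrum_id = "s", peptide = "MHHHHGHHHHK",
                     score = 5, is_decoy = FALSE, proteins = "x",
                     q_value = 0)
  map <- mapSapPeptides(psms, db)
  expect_identical(nrow(map), 1L)
  accs <- strsplit(map$accessions, ";")[[1]]
  expect_length(accs, 2L)
  expect_setequal(sub("\\|.*", "", accs), c("PX1", "PX2"))
})

test_that("wild-type collisions are excluded, with optional I/L folding", {
  # variant peptide differs from a wild-type substring only at I vs L
  wt <- c(W1 = "CCMAAAALAAAKCC", W2 = "MTTTTTTTTTK")
  saps <- data.frame(peptide = c("MAAAAIAAAK", "MGGGGGGGGGK"),
                     wildtype_peptide = c("MAAAAVAAAK", "MGGGGGGGGGK"),
                     status = "retained", stringsAsFactors = FALSE)
  off <- excludeWildtypeCollisions(saps, wt, ilEquivalence = FALSE)
  expect_identical(off$status, c("retained", "retained"))
  on <- excludeWildtypeCollisions(saps, wt, ilEquivalence = TRUE)
  expect_identical(on$status, c("wildtype_collision", "retained"))
  # verbatim occurrence is excluded regardless of mode
  hit <- data.frame(peptide = "MTTTTTTTTTK", wildtype_peptide = "x",
                    status = "retained", stringsAsFactors = FALSE)
  expect_identical(excludeWildtypeCollisions(hit, wt)$status,
                   "wildtype_collision")
})

test_that("PTM collisions move to their own bucket by set membership", {
  saps <- data.frame(peptide = c("MYYYYDYYYYK", "MVVVVGVVVVK"),
                     ref_aa = c("N", "A"), alt_aa = c("D", "G"),
                     wildtype_peptide = c("MYYYYNYYYYK", "MVVVVAVVVVK"),
                     status = "retained", stringsAsFactors = FALSE)
  out <- excludePtmCollisions(saps, ptmPeptides = "MYYYYNYYYYK",
                              builtinRules = TRUE)
  expect_identical(out$status, c("ptm_collision", "retained"))
  # deamidation mimic flagged, not excluded
  expect_identical(out$ptm_mimic, c(TRUE, FALSE))
  # empty PTM set and rules off: nothing moves
  same <- excludePtmCollisions(saps)
  expect_identical(same$status, c("retained", "retained"))
  # bucket sizes equal brute-force set membership counts
  expect_identical(sum(out$status == "ptm_collision"),
                   sum(saps$wildtype_peptide %in% "MYYYYNYYYYK"))
})

test_that("protein reassembly groups retained peptides with support counts", {
  saps <- data.frame(peptide = c("PEPTIDEONEK", "PEPTIDETWOK", "PEPTIDESIXK"),
                     accessions = c("V1", "V1", "V2"),
                     n_spectra = c(3L, 2L, 1L),
                     status = c("retained", "retained", "wildtype_collision"),
                     stringsAsFactors = FALSE)
  out <- reassembleProteins(saps)
  expect_identical(nrow(out), 1L)
  expect_identical(out$accession, "V1")
  expect_identical(out$n_peptides, 2L)
  expect_identical(out$n_spectra, 5L)   # spectra conserve across peptides
  # a >=2-peptide rule removes singly-supported proteins
  saps$status <- "retained"
  out2 <- reassembleProteins(saps, minPeptides = 2L)
  expect_identical(out2$accession, "V1")
})

test_that("the planted cascade fixture lands in the expected buckets", {
  fx <- cascade_fixture()
  res <- suppressWarnings(
    runCascade(fx$psms, fx$db, ptmPeptides = fx$ptm))
  b <- cascadeBuckets(res$report)
  expect_identical(b[["retained"]], 1L)
  expect_identical(b[["wildtype_collision"]], 1L)
  expect_identical(b[["ptm_collision"]], 1L)
  expect_identical(b[["too_short"]], 1L)
  expect_identical(b[["failed_group_fdr"]], 0L)
  expect_identical(b[["unmapped"]], 0L)
  expect_identical(res$sapPeptides$peptide, "MVVVVGVVVVK")
  expect_identical(res$ptm$peptide, "MYYYYDYYYYK")
  # terminal buckets conserve the post-FDR peptide universe
  st <- cascadeStages(res$report)
  expect_identical(sum(b), st$peptides[st$stage == "global_fdr"])
  # reassembly reports the one supported variant protein
  expect_identical(res$proteins$accession, "PROTA|SAP|A6G|s1")
  expect_identical(res$proteins$n_peptides, 1L)
})

test_that("stage counts never increase along the cascade", {
  sim <- shared_sim_db()
  cfg <- simConfig(nSpectra = 4000L, seed = 61L)
  psms <- simulatePsms(sim$db, cfg, pools = sim$pools)
  res <- runCascade(psms, sim$db)
  st <- cascadeStages(res$report)
  expect_true(all(diff(st$peptides) <= 0))
  expect_true(all(diff(st$spectra) <= 0))
  # every retained peptide satisfies all cascade criteria
  ret <- res$sapPeptides
  expect_true(all(nchar(ret$peptide) > 9))
  expect_true(all(ret$q_value <= 0.01))
  expect_true(all(ret$group_q_value <= 0.01))
  expect_true(all(substr(ret$peptide, ret$variant_offset,
                         ret$variant_offset) == ret$alt_aa))
  # wild-type counterpart inversion reproduces the peptide
  back <- ret$wildtype_peptide
  substr(back, ret$variant_offset, ret$variant_offset) <- ret$alt_aa
  expect_identical(back, ret$peptide)
})

test_that("an emptying stage yields a zero-count report, not an error", {
  fx <- cascade_fixture()
  psms <- fx$psms
  psms$score[!psms$is_decoy] <- 0.1    # every target drowns below decoys
  res <- suppressWarnings(runCascade(psms, fx$db, ptmPeptides = fx$ptm))
  st <- cascadeStages(res$report)
  expect_identical(st$peptides[st$stage == "reassembly"], 0L)
  expect_identical(nrow(res$sapPeptides), 0L)
})

test_that("the cascade is deterministic given identical input", {
  fx <- cascade_fixture()
  r1 <- suppressWarnings(runCascade(fx$psms, fx$db, ptmPeptides = fx$ptm))
  r2 <- suppressWarnings(runCascade(fx$psms, fx$db, ptmPeptides = fx$ptm))
  expect_identical(cascadeStages(r1$report), cascadeStages(r2$report))
  expect_identical(r1$sapPeptides, r2$sapPeptides)
  f1 <- tempfile(); f2 <- tempfile()
  renderCascadeReport(r1$report, f1, config = sapConfig())
  renderCascadeReport(r2$report, f2, config = sapConfig())
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})
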