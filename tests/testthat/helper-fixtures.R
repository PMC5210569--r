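## Hand-built fixtures with enumerable outcomes.

## Cascade fixture: four planted variant peptides with one known fate
## each — retained, wild-type collision, PTM collision, too short.
cascade_fixture <- function() {
  proteome <- c(
    PROTA = "MVVVVAVVVVKGGG",   # SAP A6G -> retained peptide
    PROTB = "MWWWWNWWWWKCCC",   # SAP N6S -> collides with PROTC
    PROTC = "SSMWWWWSWWWWKSS",  # wild-type home of the collision
    PROTD = "MYYYYNYYYYKDDD",   # SAP N6D -> wild-type counterpart is PTM
    PROTE = "MFFFAFFKGGG"       # SAP A5G -> covering peptide is an 8-mer
  )
  saps <- data.frame(
    protein_accession = c("PROTA", "PROTB", "PROTD", "PROTE"),
    position = c(6L, 6L, 6L, 5L),
    ref_aa = c("A", "N", "N", "A"),
    alt_aa = c("G", "S", "D", "G"),
    source_id = c("s1", "s2", "s3", "s4"),
    stringsAsFactors = FALSE)
  db <- buildSapDatabase(proteome, saps)
  psms <- data.frame(
    spectrum_id = sprintf("SP%02d", 1:6),
    peptide = c("MVVVVGVVVVK", "MWWWWSWWWWK", "MYYYYDYYYYK", "MFFFGFFK",
                "GGGK", "KVVVV"),
    score = c(10, 9.5, 9, 8.5, 1, 0.5),
    charge = 2L,
    proteins = c("PROTA|SAP|A6G|s1", "PROTB|SAP|N6S|s2", "PROTD|SAP|N6D|s3",
                 "PROTE|SAP|A5G|s4", "DECOY_PROTA", "DECOY_PROTA"),
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  list(proteome = proteome, saps = saps, db = db, psms = psms,
       ptm = "MYYYYNYYYYK")
}

## small simulated database shared by statistical tests (built once)
shared_sim_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simConfig(seed = 1L)
      proteome <- makeToyProteome(cfg)
      gen <- makeVariants(proteome, cfg)
      db <- buildSapDatabase(proteome, gen$saps)
      cache <<- list(config = cfg, proteome = proteome, gen = gen,
                     db = db, pools = peptidePools(db))
    }
    cache
  }
})

## random PSM list for property tests
random_psms <- function(n, seed) {
  set.seed(seed)
  data.frame(score = round(rnorm(n), 2),   # rounding forces score ties
             is_decoy = runif(n) < 0.4,
             stringsAsFactors = FALSE)
}
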