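## Run configuration: the tunables of the cascade, with the standard
## search/QC settings as defaults.

#' Cascade run configuration
#'
#' Bundles every tunable of the QC cascade.  The defaults encode the
#' standard settings of the workflow: global FDR at q <= 0.01, subgroup
#' (group) FDR at 0.01, peptides strictly longer than 9 residues, up to
#' 2 missed tryptic cleavages, parent-ion charge states +2..+4 and mass
#' tolerances of 20 ppm (precursor) / 0.5 Da (fragment).  The
#' tolerances and charge states are provenance only — the upstream
#' search engine applies them — but they are validated and serialized
#' into output headers so a run's settings are on record.
#'
#' @param q_max global FDR (q-value) cutoff.
#' @param group_q_max subgroup (transferred) FDR cutoff.
#' @param min_peptide_length_exclusive peptides must be strictly longer
#'   than this many residues.
#' @param missed_cleavages maximum missed tryptic cleavages.
#' @param min_digest_length minimum peptide length emitted by the
#'   in-silico digest.
#' @param charges allowed parent-ion charge states (provenance).
#' @param precursor_tol_ppm precursor mass tolerance, ppm (provenance).
#' @param fragment_tol_da fragment mass tolerance, Da (provenance).
#' @param il_equivalence treat I and L as identical in wild-type
#'   collision matching.
#' @param ptm_builtin_rules flag deamidation-mimicking substitutions.
#' @param min_peptides_per_protein support needed to report a
#'   reassembled protein.
#' @param seed integer seed recorded for stochastic steps.
#' @return a validated named list of class \code{"sapConfig"}.
#' @export
sapConfig <- function(q_max = 0.01, group_q_max = 0.01,
                      min_peptide_length_exclusive = 9L,
                      missed_cleavages = 2L, min_digest_length = 7L,
                      charges = c(2L, 3L, 4L),
                      precursor_tol_ppm = 20, fragment_tol_da = 0.5,
                      il_equivalence = FALSE, ptm_builtin_rules = FALSE,
                      min_peptides_per_protein = 1L, seed = 1L) {
  cfg <- list(q_max = q_max, group_q_max = group_q_max,
              min_peptide_length_exclusive = as.integer(min_peptide_length_exclusive),
              missed_cleavages = as.integer(missed_cleavages),
              min_digest_length = as.integer(min_digest_length),
              charges = as.integer(charges),
              precursor_tol_ppm = precursor_tol_ppm,
              fragment_tol_da = fragment_tol_da,
              il_equivalence = isTRUE(il_equivalence),
              ptm_builtin_rules = isTRUE(ptm_builtin_rules),
              min_peptides_per_protein = as.integer(min_peptides_per_protein),
              seed = as.integer(seed))
  stopifnot(cfg$q_max >= 0, cfg$q_max <= 1,
            cfg$group_q_max >= 0, cfg$group_q_max <= 1,
            cfg$min_peptide_length_exclusive >= 0L,
            cfg$missed_cleavages >= 0L, cfg$min_digest_length >= 1L,
            all(cfg$charges >= 1L), cfg$precursor_tol_ppm > 0,
            cfg$fragment_tol_da > 0, cfg$min_peptides_per_protein >= 1L)
  class(cfg) <- "sapConfig"
  cfg
}

#' @export
print.sapConfig <- function(x, ...) {
  cat("sapConfig:\n")
  for (k in names(x))
    cat(sprintf("  %-29s %s\n", k, paste(x[[k]], collapse = ",")))
  invisible(x)
}

#' Read a key=value configuration file into a sapConfig
#'
#' One \code{key=value} pair per line; blank lines and \code{#}
#' comments ignored; keys mirror the [sapConfig()] arguments and
#' multi-valued fields (\code{charges}) are comma-separated.
#'
#' @param path file path.
#' @return a [sapConfig()] list.
#' @export
readSapConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  args <- lapply(setNames(vals, keys), function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1L]])
    if (all(toupper(parts) %in% c("TRUE", "FALSE")))
      as.logical(toupper(parts))
    else if (!anyNA(suppressWarnings(as.numeric(parts))))
      as.numeric(parts)
    else parts
  })
  unknown <- setdiff(names(args), names(formals(sapConfig)))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(sapConfig, args)
}

## short stable hash of a config (provenance headers)
.config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(v, collapse = ","), ""),
             sep = "=", collapse = ";")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- ((h * 16777619) + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
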