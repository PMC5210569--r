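## Monoisotopic residue masses and isobaric-substitution flagging.

## Standard monoisotopic residue (not free amino acid) masses in Da.
.RESIDUE_MASS <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Monoisotopic residue masses of the 20 standard amino acids
#'
#' Returns the monoisotopic residue masses (mass of the amino acid minus
#' water, i.e. its contribution inside a peptide chain) in Daltons.
#' Note that isoleucine and leucine are exactly isobaric.
#'
#' @return named numeric vector of length 20 (one-letter codes).
#' @examples
#' residueMasses()[c("K", "Q")]   # differ by ~0.036 Da
#' @export
residueMasses <- function() .RESIDUE_MASS

#' Flag amino-acid substitutions that are (near-)isobaric
#'
#' Substitutions whose residue-mass difference is within the instrument's
#' discrimination limit (classically K->Q, ~0.036 Da, and L->I, 0 Da)
#' are a recognised noise source in variant peptide detection: the
#' search engine cannot reliably distinguish the reference from the
#' alternative residue.  This flags such SAPs so they can be reviewed.
#'
#' @param refAa,altAa character vectors of single-letter residue codes
#'   (recycled to common length).
#' @param toleranceDa non-negative mass tolerance in Da; default 0.05.
#' @return logical vector: \code{TRUE} where
#'   \eqn{|m(alt) - m(ref)| \le} \code{toleranceDa}.
#' @examples
#' flagIsobaric("L", "I")                    # TRUE at any tolerance
#' flagIsobaric("K", "Q", toleranceDa = 0.01) # FALSE: 0.036 Da apart
#' @export
flagIsobaric <- function(refAa, altAa, toleranceDa = 0.05) {
  stopifnot(is.numeric(toleranceDa), length(toleranceDa) == 1L,
            toleranceDa >= 0)
  bad <- setdiff(unique(c(refAa, altAa)), names(.RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  unname(abs(.RESIDUE_MASS[altAa] - .RESIDUE_MASS[refAa]) <= toleranceDa)
}
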