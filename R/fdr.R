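## Target-decoy global FDR / q-values and the subgroup ("transferred")
## FDR for mutation-carrying peptide identifications.

## counts of sorted-ascending vector `vec` that are >= each x
.count_ge <- function(x, vec_sorted)
  length(vec_sorted) - findInterval(x, vec_sorted, left.open = TRUE)

#' Target-decoy q-values for a PSM table
#'
#' Ranks PSMs by descending score and estimates, at every distinct
#' score threshold \eqn{s}, the false discovery rate
#' FDR(\eqn{s}) = #\{decoys with score \eqn{\ge s}\} /
#' #\{targets with score \eqn{\ge s}\} (ties share a threshold; a PSM
#' counts itself at its own score).  The q-value of a PSM is the
#' minimum FDR over its own and all lower thresholds (monotonized), so
#' q-values never increase with score.  Decoy PSMs receive the q-value
#' of their own score threshold for diagnostic use.
#'
#' @param psms data.frame with numeric \code{score} and logical
#'   \code{is_decoy}.
#' @param conservative add the +1 pseudo-count to the decoy numerator
#'   (off by default: the plain ratio).
#' @return \code{psms} with a \code{q_value} column appended.
#' @examples
#' p <- data.frame(score = c(10, 9, 8, 7, 9.5, 6),
#'                 is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
#' computeQvalues(p)$q_value   # targets: 0, .25, .25, .25
#' @export
computeQvalues <- function(psms, conservative = FALSE) {
  stopifnot(is.data.frame(psms), all(c("score", "is_decoy") %in% names(psms)))
  if (nrow(psms) == 0L) { psms$q_value <- numeric(0); return(psms) }
  stopifnot(all(is.finite(psms$score)))
  if (!any(!psms$is_decoy)) stop("no target PSMs: q-values undefined")
  if (!any(psms$is_decoy)) {
    warning("no decoy PSMs: all q-values are 0")
    psms$q_value <- 0
    return(psms)
  }
  ts <- sort(psms$score[!psms$is_decoy])
  ds <- sort(psms$score[psms$is_decoy])
  thr <- sort(unique(psms$score), decreasing = TRUE)
  nt <- .count_ge(thr, ts)
  nd <- .count_ge(thr, ds) + as.integer(conservative)
  fdr <- ifelse(nt == 0L, Inf, nd / nt)
  q <- pmin(1, rev(cummin(rev(fdr))))
  psms$q_value <- q[match(psms$score, thr)]
  psms
}

#' Global target-decoy FDR at a score threshold
#'
#' The plain target-decoy estimate among identifications above a
#' threshold: #decoys / #targets with score beyond \code{x}.  The
#' published formulation counts strictly greater scores; set
#' \code{inclusive = TRUE} to count a PSM at its own score.
#'
#' @param x numeric threshold (vectorized).
#' @param psms data.frame with \code{score} and \code{is_decoy}.
#' @param inclusive count scores \eqn{\ge x} instead of \eqn{> x}.
#' @return numeric vector of FDR estimates; 0 (with a warning) where no
#'   target exceeds the threshold.
#' @export
globalFdrAt <- function(x, psms, inclusive = FALSE) {
  ts <- sort(psms$score[!psms$is_decoy])
  ds <- sort(psms$score[psms$is_decoy])
  cnt <- function(v) if (inclusive) .count_ge(x, v)
                     else length(v) - findInterval(x, v)
  nt <- cnt(ts); nd <- cnt(ds)
  if (any(nt == 0L))
    warning("no target identifications above some threshold(s); FDR set to 0")
  ifelse(nt == 0L, 0, nd / nt)
}

#' Fit the linear model of the mutation fraction among false hits
#'
#' The transferred FDR needs \eqn{\gamma_k(x)}, the probability that a
#' false identification scoring beyond \eqn{x} carries a mutation,
#' approximated by a straight line \eqn{a x + b}.  The coefficients are
#' estimated from the decoy PSM population, the observable stand-in for
#' false identifications: decoy scores are partitioned into
#' quantile-based cells, the mutation fraction in each cell is
#' regressed (ordinary least squares) on the mean decoy score of the
#' cell.  Cells with fewer than \code{minCount} observations are merged
#' with their neighbour.  When fewer than two usable cells remain (or
#' the score spread is degenerate) the fit falls back to a constant:
#' slope 0 and the pooled mutation fraction as intercept, with a
#' warning.
#'
#' With \code{mode = "cumulative"} the observations are instead the
#' mutation fractions among all decoys above each grid threshold, the
#' running-tail form in which \eqn{\gamma_k} enters the FDR formula;
#' these tail averages smooth over the score dependence, so the default
#' per-cell ("binned") mode is used to estimate the line itself.
#'
#' @param psms data.frame with \code{score}, logical \code{is_decoy}
#'   and logical \code{is_mutation} (mutation-carrying peptide).
#' @param nCells number of quantile cells over the decoy scores.
#' @param minCount minimum decoy observations per cell.
#' @param mode \code{"binned"} (default) or \code{"cumulative"}.
#' @return a [GammaFit-class].
#' @seealso [predictGamma()], [transferredFdr()]
#' @export
fitGamma <- function(psms, nCells = 20L, minCount = 10L,
                     mode = c("binned", "cumulative")) {
  mode <- match.arg(mode)
  stopifnot(all(c("score", "is_decoy", "is_mutation") %in% names(psms)))
  dec <- psms[psms$is_decoy & !is.na(psms$is_mutation), , drop = FALSE]
  pooled <- if (nrow(dec)) mean(dec$is_mutation) else 0
  fallback <- function(msg) {
    warning("fitGamma: ", msg, "; falling back to constant fit")
    new("GammaFit", a = 0, b = pooled,
        scoreGrid = range(c(dec$score, 0, 1)), cellScore = numeric(0),
        gammaObserved = numeric(0), cellCounts = integer(0),
        fallback = TRUE, mode = mode)
  }
  if (nrow(dec) < 2L * minCount || length(unique(dec$score)) < 2L)
    return(fallback("too few decoy observations"))
  breaks <- unique(quantile(dec$score, probs = seq(0, 1, length.out = nCells + 1L),
                            names = FALSE, type = 7))
  if (length(breaks) < 3L)
    return(fallback("degenerate decoy score distribution"))
  if (mode == "binned") {
    cell <- findInterval(dec$score, breaks, rightmost.closed = TRUE,
                         all.inside = TRUE)
    cnt <- tabulate(cell, nbins = length(breaks) - 1L)
    ## greedy left-to-right merge of undersized cells
    grpid <- integer(length(cnt)); g <- 1L; acc <- 0L
    for (j in seq_along(cnt)) {
      grpid[j] <- g
      acc <- acc + cnt[j]
      if (acc >= minCount && j < length(cnt)) { g <- g + 1L; acc <- 0L }
    }
    if (acc < minCount && acc > 0L && g > 1L)   # fold trailing remnant back
      grpid[grpid == g] <- g - 1L
    grp <- factor(grpid[cell], levels = sort(unique(grpid[cell])))
    xs <- as.numeric(tapply(dec$score, grp, mean))
    ys <- as.numeric(tapply(as.numeric(dec$is_mutation), grp, mean))
    ns <- as.integer(tapply(dec$score, grp, length))
  } else {
    thr <- breaks[-length(breaks)]
    ds <- sort(dec$score)
    ms <- sort(dec$score[dec$is_mutation])
    ntail <- .count_ge(thr, ds)
    keep <- ntail >= minCount
    xs <- thr[keep]
    ys <- .count_ge(xs, ms) / ntail[keep]
    ns <- ntail[keep]
  }
  if (length(xs) < 2L || sd(xs) == 0)
    return(fallback("fewer than two usable score cells"))
  fit <- lm(ys ~ xs)
  new("GammaFit", a = unname(coef(fit)[2L]), b = unname(coef(fit)[1L]),
      scoreGrid = as.numeric(breaks), cellScore = as.numeric(xs),
      gammaObserved = as.numeric(ys), cellCounts = as.integer(ns),
      fallback = FALSE, mode = mode)
}

#' @describeIn GammaFit-class evaluate the fitted line
#'   \eqn{\hat a x + \hat b}, clamped to \eqn{[0, 1]}.
#' @export
setMethod("predictGamma", "GammaFit", function(fit, x)
  pmin(1, pmax(0, fit@a * x + fit@b)))

setMethod("show", "GammaFit", function(object) {
  cat(sprintf("GammaFit: gamma_k(x) ~= %.4g * x + %.4g  (%s%s, %d cells)\n",
              object@a, object@b, object@mode,
              if (object@fallback) ", constant fallback" else "",
              length(object@gammaObserved)))
})

#' Transferred (subgroup) FDR for mutation peptides at a threshold
#'
#' The subgroup FDR of mutation-carrying identifications scoring beyond
#' \eqn{x} is derived from the global FDR rather than estimated from
#' the sparse mutation subgroup itself:
#' \deqn{FDR_k(x) = \frac{N(x)}{N_k(x)} \, (\hat a x + \hat b) \, FDR(x)}
#' where \eqn{N(x)} and \eqn{N_k(x)} count all and mutation-carrying
#' target identifications beyond the threshold, and the linear factor
#' is the fitted mutation fraction among false identifications
#' ([fitGamma()]), clamped to \eqn{[0, 1]}.  The result is clamped to
#' \eqn{[0, 1]} as well.
#'
#' @param x score threshold(s).
#' @param n \eqn{N(x)}: target identifications beyond \code{x}.
#' @param nk \eqn{N_k(x)}: mutation-carrying target identifications
#'   beyond \code{x}; where 0 the estimate is undefined and \code{NA}
#'   is returned.
#' @param fit a [GammaFit-class].
#' @param fdrGlobal the global FDR estimate(s) at \code{x}.
#' @return numeric vector of transferred-FDR estimates in
#'   \eqn{[0, 1]}, \code{NA} where \code{nk} is 0.
#' @examples
#' fit <- new("GammaFit", a = 0, b = 0.04, scoreGrid = c(0, 1),
#'            cellScore = numeric(0), gammaObserved = numeric(0),
#'            cellCounts = integer(0), fallback = TRUE, mode = "binned")
#' transferredFdr(5, n = 100, nk = 5, fit = fit, fdrGlobal = 0.01)  # 0.008
#' @export
transferredFdr <- function(x, n, nk, fit, fdrGlobal) {
  stopifnot(is(fit, "GammaFit"))
  out <- ifelse(nk >= 1L,
                pmin(1, pmax(0, (n / pmax(nk, 1L)) * predictGamma(fit, x) *
                                fdrGlobal)),
                NA_real_)
  as.numeric(out)
}

#' Subgroup q-values for mutation-carrying PSMs
#'
#' Evaluates the transferred FDR at every distinct score of a
#' mutation-carrying target PSM (counting each PSM at its own score)
#' and monotonizes over descending score into a subgroup q-value,
#' stored as \code{group_q_value} on mutation target PSMs; all other
#' PSMs get \code{NA}.
#'
#' @param psms data.frame with \code{score}, \code{is_decoy},
#'   \code{is_mutation} and (from [computeQvalues()]) \code{q_value}.
#' @param fit a [GammaFit-class]; fitted from \code{psms} when missing.
#' @return \code{psms} with a \code{group_q_value} column appended.
#' @export
groupQvalues <- function(psms, fit = NULL) {
  stopifnot(all(c("score", "is_decoy", "is_mutation") %in% names(psms)))
  if (!"q_value" %in% names(psms))
    stop("run computeQvalues() before groupQvalues()")
  if (is.null(fit)) fit <- fitGamma(psms)
  psms$group_q_value <- NA_real_
  mut <- !psms$is_decoy & psms$is_mutation %in% TRUE
  if (!any(mut)) {
    warning("no mutation-carrying target PSMs; group q-values not computed")
    return(psms)
  }
  ts <- sort(psms$score[!psms$is_decoy])
  ms <- sort(psms$score[mut])
  ds <- sort(psms$score[psms$is_decoy])
  thr <- sort(unique(psms$score[mut]), decreasing = TRUE)
  n <- .count_ge(thr, ts)
  nk <- .count_ge(thr, ms)
  fdr <- if (length(ds)) .count_ge(thr, ds) / n else rep(0, length(thr))
  tf <- transferredFdr(thr, n, nk, fit, fdr)
  gq <- pmin(1, rev(cummin(rev(tf))))
  psms$group_q_value[mut] <- gq[match(psms$score[mut], thr)]
  psms
}

#' Global and transferred FDR as a function of the score threshold
#'
#' Tabulates, over the distinct observed scores (or a supplied grid),
#' the target and mutation-target counts, the global target-decoy FDR,
#' the fitted \eqn{\gamma_k} and the transferred FDR — the curve behind
#' the subgroup q-values.
#'
#' @param psms scored PSM table with \code{is_mutation}.
#' @param fit a [GammaFit-class]; fitted from \code{psms} when missing.
#' @param thresholds numeric grid; defaults to the distinct target
#'   scores.
#' @return data.frame with columns \code{x}, \code{N}, \code{N_k},
#'   \code{FDR}, \code{gamma_hat}, \code{FDR_k}.
#' @export
fdrCurve <- function(psms, fit = NULL, thresholds = NULL) {
  if (is.null(fit)) fit <- fitGamma(psms)
  if (is.null(thresholds))
    thresholds <- sort(unique(psms$score[!psms$is_decoy]), decreasing = TRUE)
  ts <- sort(psms$score[!psms$is_decoy])
  ms <- sort(psms$score[!psms$is_decoy & psms$is_mutation %in% TRUE])
  ds <- sort(psms$score[psms$is_decoy])
  n <- .count_ge(thresholds, ts)
  nk <- .count_ge(thresholds, ms)
  fdr <- ifelse(n == 0L, 0, .count_ge(thresholds, ds) / pmax(n, 1L))
  data.frame(x = thresholds, N = n, N_k = nk, FDR = fdr,
             gamma_hat = predictGamma(fit, thresholds),
             FDR_k = transferredFdr(thresholds, n, nk, fit, fdr))
}
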