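#' @rdname SapDatabase-class
#' @param x a \code{SapDatabase}.
#' @export
setGeneric("proteinSequences", function(x) standardGeneric("proteinSequences"))

#' @rdname SapDatabase-class
#' @export
setGeneric("entryInfo", function(x) standardGeneric("entryInfo"))

#' @rdname SapDatabase-class
#' @export
setGeneric("sapTable", function(x) standardGeneric("sapTable"))

#' @rdname SapDatabase-class
#' @export
setGeneric("targetEntries", function(x) standardGeneric("targetEntries"))

#' @rdname SapDatabase-class
#' @export
setGeneric("decoyEntries", function(x) standardGeneric("decoyEntries"))

#' @rdname GammaFit-class
#' @param fit a \code{GammaFit}.
#' @param x numeric vector of score thresholds.
#' @export
setGeneric("predictGamma", function(fit, x) standardGeneric("predictGamma"))

#' @rdname CascadeReport-class
#' @param report a \code{CascadeReport}.
#' @export
setGeneric("cascadeStages", function(report) standardGeneric("cascadeStages"))

#' @rdname CascadeReport-class
#' @export
setGeneric("cascadeBuckets", function(report) standardGeneric("cascadeBuckets"))
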