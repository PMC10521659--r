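#' @include qsanger-package.R
NULL

#' Accessors for trace objects
#'
#' `channels()` returns the 4-column amplitude matrix (columns `G`, `A`, `T`,
#' `C`), `peakTimes()` the per-base peak sample indices, `basecalls()` the
#' called sequence, and `sampleId()` the free-text identifier.
#'
#' @param x a [Chromatogram] or [WarpedTrace].
#' @return `channels()`: numeric matrix; `peakTimes()`: integer vector;
#'   `basecalls()`: character scalar; `sampleId()`: character scalar.
#' @name trace-accessors
#' @aliases channels peakTimes basecalls sampleId
#' @examples
#' cg <- Chromatogram(matrix(0, 10, 4, dimnames = list(NULL, c("G","A","T","C"))),
#'                    peakTimes = c(3L, 7L), basecalls = "GA")
#' peakTimes(cg)
NULL

#' @rdname trace-accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname trace-accessors
#' @export
setGeneric("peakTimes", function(x) standardGeneric("peakTimes"))

#' @rdname trace-accessors
#' @export
setGeneric("basecalls", function(x) standardGeneric("basecalls"))

#' @rdname trace-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' Accessors for mixture-fraction estimates
#'
#' @param x a [RatioEstimate].
#' @return `omega()`: the estimated fraction of variant 1 in `[0, 1]`;
#'   `residualError()`: the least-squares objective at the optimum;
#'   `nInformative()` / `nMismatch()`: counts of divergent columns used and
#'   of mismatch columns excluded.
#' @name estimate-accessors
#' @aliases omega residualError nInformative nMismatch
NULL

#' @rdname estimate-accessors
#' @export
setGeneric("omega", function(x) standardGeneric("omega"))

#' @rdname estimate-accessors
#' @export
setGeneric("residualError", function(x) standardGeneric("residualError"))

#' @rdname estimate-accessors
#' @export
setGeneric("nInformative", function(x) standardGeneric("nInformative"))

#' @rdname estimate-accessors
#' @export
setGeneric("nMismatch", function(x) standardGeneric("nMismatch"))
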