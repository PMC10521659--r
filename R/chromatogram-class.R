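#' @include AllGenerics.R
NULL

BASES <- c("G", "A", "T", "C")

#' Chromatogram: a 4-channel Sanger trace with called peaks
#'
#' The raw material of the pipeline: one non-negative amplitude series per
#' dye channel (`G`, `A`, `T`, `C`), the sample index of each called base's
#' peak, and the called sequence itself. Sample indices are 1-based.
#'
#' @slot channels numeric matrix, `T` rows by 4 columns named `G`, `A`, `T`,
#'   `C`; arbitrary fluorescence units, all values `>= 0`.
#' @slot peakTimes integer vector of strictly increasing sample indices in
#'   `[1, T]`, one per called base.
#' @slot basecalls single character string of called letters (may use IUPAC
#'   two-base codes for mixed reads); either empty or of
#'   `length(peakTimes)` characters.
#' @slot sampleId free-text identifier.
#' @slot baseOffset number of leading called bases of the original read that
#'   [trimRead()] has already discarded; keeps trimming idempotent and base
#'   coordinates traceable to the untrimmed read.
#'
#' @param channels,peakTimes,basecalls,sampleId,baseOffset see slots above.
#' @return `Chromatogram()` returns a validated `Chromatogram` object.
#'
#' @examples
#' amp <- matrix(0, 30, 4, dimnames = list(NULL, c("G", "A", "T", "C")))
#' amp[10, "G"] <- 900; amp[20, "A"] <- 850
#' cg <- Chromatogram(amp, peakTimes = c(10L, 20L), basecalls = "GA")
#' cg
#' @aliases Chromatogram
#' @export Chromatogram
#' @exportClass Chromatogram
setClass("Chromatogram",
    representation(
        channels  = "matrix",
        peakTimes = "integer",
        basecalls = "character",
        sampleId  = "character",
        baseOffset = "integer"
    ),
    prototype(
        channels  = matrix(numeric(0), 0, 4, dimnames = list(NULL, BASES)),
        peakTimes = integer(0),
        basecalls = "",
        sampleId  = "",
        baseOffset = 0L
    )
)

setValidity("Chromatogram", function(object) {
    ch <- object@channels
    msg <- character(0)
    if (ncol(ch) != 4L || !identical(colnames(ch), BASES))
        msg <- c(msg, "channels must have 4 columns named G, A, T, C")
    if (nrow(ch) < 1L)
        msg <- c(msg, "channels must contain at least one sample (T >= 1)")
    if (anyNA(ch) || any(ch < 0))
        msg <- c(msg, "channel amplitudes must be non-negative and non-NA")
    pt <- object@peakTimes
    if (length(pt)) {
        if (any(pt < 1L) || any(pt > nrow(ch)))
            msg <- c(msg, "peakTimes must lie in [1, T]")
        if (any(diff(pt) <= 0L))
            msg <- c(msg, "peakTimes must be strictly increasing")
    }
    if (length(object@basecalls) != 1L)
        msg <- c(msg, "basecalls must be a single string")
    else if (nzchar(object@basecalls) &&
             nchar(object@basecalls) != length(pt))
        msg <- c(msg, "basecalls length must equal number of peaks")
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "sampleId must be a single string")
    if (length(object@baseOffset) != 1L || is.na(object@baseOffset) ||
        object@baseOffset < 0L)
        msg <- c(msg, "baseOffset must be a single non-negative integer")
    if (length(msg)) msg else TRUE
})

Chromatogram <- function(channels, peakTimes = integer(0), basecalls = "",
                         sampleId = "", baseOffset = 0L) {
    channels <- as.matrix(channels)
    mode(channels) <- "numeric"
    if (is.null(colnames(channels)) && ncol(channels) == 4L)
        colnames(channels) <- BASES
    new("Chromatogram", channels = channels,
        peakTimes = as.integer(peakTimes),
        basecalls = as.character(basecalls), sampleId = as.character(sampleId),
        baseOffset = as.integer(baseOffset))
}

#' @rdname trace-accessors
setMethod("channels", "Chromatogram", function(x) x@channels)

#' @rdname trace-accessors
setMethod("peakTimes", "Chromatogram", function(x) x@peakTimes)

#' @rdname trace-accessors
setMethod("basecalls", "Chromatogram", function(x) x@basecalls)

#' @rdname trace-accessors
setMethod("sampleId", "Chromatogram", function(x) x@sampleId)

setMethod("length", "Chromatogram", function(x) length(x@peakTimes))

setMethod("show", "Chromatogram", function(object) {
    cat("Chromatogram", sQuote(object@sampleId), "\n")
    cat("  samples:", nrow(object@channels),
        " called bases:", length(object@peakTimes), "\n")
    if (nzchar(object@basecalls)) {
        s <- object@basecalls
        if (nchar(s) > 50) s <- paste0(substr(s, 1, 50), "...")
        cat("  calls:  ", s, "\n")
    }
    invisible(NULL)
})

#' WarpedTrace: a reference trace mapped onto the mixed read's time grid
#'
#' Produced by [timeStretch()]: the four channels of a reference read,
#' resampled (piecewise-linearly between anchors) onto the mixed read's
#' sample grid over the closed anchor span `[offset, offset + n - 1]`.
#'
#' @slot channels numeric matrix, one row per mixed-grid sample on the span.
#' @slot offset 1-based mixed-grid index of the first row (the first anchor
#'   time).
#' @slot sourceId identifier of the reference read.
#' @aliases WarpedTrace
#' @exportClass WarpedTrace
setClass("WarpedTrace",
    representation(channels = "matrix", offset = "integer",
                   sourceId = "character"))

setValidity("WarpedTrace", function(object) {
    if (!identical(colnames(object@channels), BASES))
        return("channels must have columns G, A, T, C")
    if (anyNA(object@channels) || any(object@channels < -1e-9))
        return("warped amplitudes must be non-negative")
    if (length(object@offset) != 1L || object@offset < 1L)
        return("offset must be a positive scalar index")
    TRUE
})

#' @rdname trace-accessors
setMethod("channels", "WarpedTrace", function(x) x@channels)

#' @rdname trace-accessors
setMethod("sampleId", "WarpedTrace", function(x) x@sourceId)

setMethod("show", "WarpedTrace", function(object) {
    cat("WarpedTrace from", sQuote(object@sourceId), "on mixed grid [",
        object@offset, ",", object@offset + nrow(object@channels) - 1L, "]\n")
    invisible(NULL)
})

# value of a warped channel at integer mixed-grid times (NA outside span)
warpedAt <- function(w, base, t) {
    i <- t - w@offset + 1L
    out <- rep(NA_real_, length(t))
    ok <- i >= 1L & i <= nrow(w@channels)
    out[ok] <- w@channels[i[ok], base]
    out
}

#' AmplitudeScale: per-time gain aligning reference to mixed amplitudes
#'
#' Produced by [amplitudeScale()]: gains `lambda1(t)`, `lambda2(t)` on the
#' mixed read's sample grid, linear between anchor-point amplitude ratios.
#' They absorb the run-to-run differences in overall signal level and decay.
#'
#' @slot lambda1,lambda2 numeric gain series on the span.
#' @slot offset 1-based mixed-grid index of the first element.
#' @slot anchorRatios data.frame of per-anchor (time, ratio1, ratio2), with
#'   NA where an anchor had no usable denominator.
#' @aliases AmplitudeScale
#' @exportClass AmplitudeScale
setClass("AmplitudeScale",
    representation(lambda1 = "numeric", lambda2 = "numeric",
                   offset = "integer", anchorRatios = "data.frame"))

setValidity("AmplitudeScale", function(object) {
    if (length(object@lambda1) != length(object@lambda2))
        return("lambda1 and lambda2 must have equal length")
    if (any(!is.finite(object@lambda1)) || any(!is.finite(object@lambda2)))
        return("gains must be finite")
    TRUE
})

setMethod("show", "AmplitudeScale", function(object) {
    cat("AmplitudeScale on mixed grid [", object@offset, ",",
        object@offset + length(object@lambda1) - 1L, "]; lambda1 in [",
        signif(min(object@lambda1), 3), ",", signif(max(object@lambda1), 3),
        "], lambda2 in [", signif(min(object@lambda2), 3), ",",
        signif(max(object@lambda2), 3), "]\n")
    invisible(NULL)
})

lambdaAt <- function(s, which, t) {
    v <- if (which == 1L) s@lambda1 else s@lambda2
    i <- t - s@offset + 1L
    out <- rep(NA_real_, length(t))
    ok <- i >= 1L & i <= length(v)
    out[ok] <- v[i[ok]]
    out
}

#' RatioEstimate: the estimated mixture fraction with diagnostics
#'
#' @slot omega estimated fraction of variant 1, clamped to `[0, 1]`.
#' @slot residual the least-squares objective evaluated at `omega`.
#' @slot nInformative number of divergent columns that contributed.
#' @slot nMismatch number of divergent columns where a mixed peak matched
#'   neither reference (excluded from the fit).
#' @slot window the post-trim base-index window used.
#' @slot diagnostics list: `nAnchors`, `alignmentScore`, `perColumnOmega`,
#'   plus a `config` echo when produced by [quantifyMixture()].
#' @aliases RatioEstimate
#' @exportClass RatioEstimate
setClass("RatioEstimate",
    representation(omega = "numeric", residual = "numeric",
                   nInformative = "integer", nMismatch = "integer",
                   window = "integer", diagnostics = "list"))

setValidity("RatioEstimate", function(object) {
    if (object@omega < 0 || object@omega > 1)
        return("omega must lie in [0, 1]")
    if (object@residual < 0) return("residual must be non-negative")
    if (object@nInformative < 1L)
        return("an estimate requires at least one informative column")
    TRUE
})

#' @rdname estimate-accessors
setMethod("omega", "RatioEstimate", function(x) x@omega)

#' @rdname estimate-accessors
setMethod("residualError", "RatioEstimate", function(x) x@residual)

#' @rdname estimate-accessors
setMethod("nInformative", "RatioEstimate", function(x) x@nInformative)

#' @rdname estimate-accessors
setMethod("nMismatch", "RatioEstimate", function(x) x@nMismatch)

setMethod("show", "RatioEstimate", function(object) {
    cat(sprintf("RatioEstimate: omega = %.4f (variant 1 fraction)\n",
                object@omega))
    cat(sprintf("  residual %.4g over %d informative columns (%d mismatch)\n",
                object@residual, object@nInformative, object@nMismatch))
    if (!is.null(object@diagnostics$nAnchors))
        cat("  anchors:", object@diagnostics$nAnchors,
            " window:", paste(object@window, collapse = "-"), "\n")
    invisible(NULL)
})

#' Export a RatioEstimate as a JSON report
#'
#' Writes (or returns) the machine-readable report produced at the end of a
#' quantification run: `omega`, `residual`, column counts, anchor count,
#' alignment score, window and the configuration echo.
#'
#' @param est a [RatioEstimate].
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
ratioReport <- function(est, path = NULL) {
    stopifnot(is(est, "RatioEstimate"))
    rep <- list(
        omega = est@omega, residual = est@residual,
        n_informative = est@nInformative, n_mismatch = est@nMismatch,
        window = as.integer(est@window),
        n_anchors = est@diagnostics$nAnchors,
        alignment_score = est@diagnostics$alignmentScore,
        config = est@diagnostics$config
    )
    js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}
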