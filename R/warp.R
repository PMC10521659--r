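#' @include align.R
NULL

#' Warp a reference trace onto the mixed read's time grid
#'
#' Between consecutive anchors the reference time axis is stretched
#' linearly so that anchor peaks coincide with the mixed read's anchor
#' peaks; within a segment the query time `t` samples the reference at
#' `tRef_k + (t - tM_k) / (tM_{k+1} - tM_k) * (tRef_{k+1} - tRef_k)`,
#' with linear interpolation of channel values at fractional sample
#' positions. The warped trace is defined exactly on the closed anchor span
#' of the mixed grid and is exact at every anchor.
#'
#' @param ref the reference [Chromatogram].
#' @param anchors anchor table from [selectAnchors()].
#' @param frame `"p1"` or `"p2"`: which reference time column to use.
#' @return a [WarpedTrace] on mixed-grid samples
#'   `anchors$tM[1] : anchors$tM[n]`.
#' @export
timeStretch <- function(ref, anchors, frame = c("p1", "p2")) {
    frame <- match.arg(frame)
    tM <- anchors$tM
    tR <- if (frame == "p1") anchors$tP1 else anchors$tP2
    if (length(tM) < 2L) stop("time stretching needs at least 2 anchors")
    if (any(diff(tM) <= 0) || any(diff(tR) <= 0))
        stop("anchor times must be strictly increasing in both frames")
    grid <- tM[1]:tM[length(tM)]
    refTime <- approx(tM, tR, xout = grid)$y
    ch <- channels(ref)
    warped <- matrix(0, length(grid), 4, dimnames = list(NULL, BASES))
    for (b in BASES)
        warped[, b] <- approx(seq_len(nrow(ch)), ch[, b], xout = refTime)$y
    warped[warped < 0] <- 0
    new("WarpedTrace", channels = warped, offset = as.integer(grid[1]),
        sourceId = sampleId(ref))
}

#' Per-time amplitude gains between mixed and warped reference traces
#'
#' At each anchor the gain is the ratio of the mixed amplitude to the warped
#' reference amplitude, taken on the anchor base's channel (the only channel
#' carrying signal at a pure single-peak position). Between consecutive
#' anchors the gain is linearly interpolated; beyond the outermost usable
#' anchors it is held constant. Anchors whose reference amplitude is zero
#' carry no gain information and are skipped, the interpolation bridging to
#' the next usable anchor. The gains absorb run-to-run differences in
#' overall signal level and in exponential signal decay.
#'
#' @param mixed the mixed [Chromatogram].
#' @param w1,w2 [WarpedTrace]s of the two references (from [timeStretch()]).
#' @param anchors anchor table from [selectAnchors()].
#' @return an [AmplitudeScale] with gains `lambda1`, `lambda2` on the anchor
#'   span of the mixed grid.
#' @export
amplitudeScale <- function(mixed, w1, w2, anchors) {
    chM <- channels(mixed)
    n <- nrow(anchors)
    ratio1 <- ratio2 <- rep(NA_real_, n)
    for (k in seq_len(n)) {
        b <- anchors$base[k]
        t <- anchors$tM[k]
        num <- chM[t, b]
        d1 <- warpedAt(w1, b, t)
        d2 <- warpedAt(w2, b, t)
        if (!is.na(d1) && d1 > 0) ratio1[k] <- num / d1
        if (!is.na(d2) && d2 > 0) ratio2[k] <- num / d2
    }
    grid <- w1@offset:(w1@offset + nrow(w1@channels) - 1L)
    interpGain <- function(ratio) {
        ok <- !is.na(ratio)
        if (!any(ok)) stop("no usable gain anchors (all zero-denominator)")
        if (sum(ok) == 1L) return(rep(ratio[ok], length(grid)))
        approx(anchors$tM[ok], ratio[ok], xout = grid, rule = 2)$y
    }
    new("AmplitudeScale", lambda1 = interpGain(ratio1),
        lambda2 = interpGain(ratio2), offset = as.integer(grid[1]),
        anchorRatios = data.frame(time = anchors$tM, ratio1 = ratio1,
                                  ratio2 = ratio2))
}
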