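#' @include warp.R
NULL

#' Select the columns that carry mixture information
#'
#' The mixture fraction can only be read off positions where the two
#' references disagree. A column is *informative* when it is gap-free, its
#' post-trim mixed base position lies inside the quality window, the
#' reference bases differ, and every mixed peak (one or two) belongs to the
#' reference pair `{p1, p2}`. Divergent columns where some mixed peak
#' matches neither reference are *mismatches*: they are excluded from the
#' fit and counted in the `nMismatch` metadata entry.
#'
#' @param cols alignment columns from [alignTraces()].
#' @param window inclusive post-trim base-position window (default
#'   `c(20, 600)`).
#' @return the informative subset of `cols`, with `metadata()` entries
#'   `nMismatch` and `window`. Zero informative columns is an error — the
#'   sequences do not diverge inside the window and no ratio is defined.
#' @export
informativeColumns <- function(cols, window = c(20, 600)) {
    gapFree <- !is.na(cols$mIndex) & !is.na(cols$p1Index) &
        !is.na(cols$p2Index)
    inWin <- gapFree & cols$mIndex >= window[1] & cols$mIndex <= window[2]
    divergent <- inWin & cols$p1Base != cols$p2Base
    consistent <- logical(nrow(cols))
    for (k in which(divergent)) {
        refPair <- c(cols$p1Base[k], cols$p2Base[k])
        peaks <- c(cols$mPrimary[k], cols$mSecondary[k])
        peaks <- peaks[!is.na(peaks)]
        consistent[k] <- length(peaks) > 0L && all(peaks %in% refPair)
    }
    out <- cols[divergent & consistent, ]
    if (nrow(out) == 0L)
        stop("sequences do not diverge in window: no informative columns")
    S4Vectors::metadata(out) <- c(S4Vectors::metadata(cols),
                                  list(nMismatch = sum(divergent &
                                                       !consistent),
                                       window = as.integer(window)))
    out
}

# sample support and regressors for the least-squares fit
omegaDesign <- function(mixed, w1, w2, scale, informative, config) {
    ptM <- peakTimes(mixed)
    chM <- channels(mixed)
    span <- c(max(w1@offset, w2@offset, scale@offset),
              min(w1@offset + nrow(w1@channels),
                  w2@offset + nrow(w2@channels),
                  scale@offset + length(scale@lambda1)) - 1L)
    h <- max(1L, as.integer(round(stats::median(diff(ptM)) / 2)))
    bM <- f1 <- f2 <- numeric(0)
    colId <- integer(0)
    if (config$integration == "informative") {
        for (k in seq_len(nrow(informative))) {
            tK <- ptM[informative$mIndex[k]]
            tt <- max(tK - h, span[1]):min(tK + h, span[2])
            if (length(tt) == 0L || tt[1] > tt[length(tt)]) next
            for (b in c(informative$p1Base[k], informative$p2Base[k])) {
                l1 <- lambdaAt(scale, 1L, tt)
                l2 <- lambdaAt(scale, 2L, tt)
                bM <- c(bM, chM[tt, b])
                f1 <- c(f1, l1 * warpedAt(w1, b, tt))
                f2 <- c(f2, l2 * warpedAt(w2, b, tt))
                colId <- c(colId, rep(k, length(tt)))
            }
        }
    } else {
        lo <- max(span[1], ptM[min(config$windowStart, length(ptM))])
        hi <- min(span[2], ptM[min(config$windowEnd, length(ptM))])
        tt <- lo:hi
        l1 <- lambdaAt(scale, 1L, tt)
        l2 <- lambdaAt(scale, 2L, tt)
        for (b in BASES) {
            bM <- c(bM, chM[tt, b])
            f1 <- c(f1, l1 * warpedAt(w1, b, tt))
            f2 <- c(f2, l2 * warpedAt(w2, b, tt))
            colId <- c(colId, rep(0L, length(tt)))
        }
    }
    ok <- is.finite(bM) & is.finite(f1) & is.finite(f2)
    list(bM = bM[ok], f1 = f1[ok], f2 = f2[ok], colId = colId[ok])
}

closedFormOmega <- function(bM, f1, f2) {
    d <- f1 - f2
    den <- sum(d * d)
    if (den <= .Machine$double.eps * max(1, sum(bM^2)))
        return(NA_real_)
    sum((bM - f2) * d) / den
}

#' Estimate the mixture fraction by least squares
#'
#' Minimizes `sum_t (bM(t) - omega * lambda1(t) * w1(t) -
#' (1 - omega) * lambda2(t) * w2(t))^2` over `omega` in `[0, 1]`, where the
#' sum runs over samples within half a peak spacing of each informative
#' column's mixed peak time, on the two divergent bases' channels. The
#' minimizer has the closed form `omega = sum((bM - f2) * (f1 - f2)) /
#' sum((f1 - f2)^2)` with `f1 = lambda1 * w1`, `f2 = lambda2 * w2`, clamped
#' to `[0, 1]`; the residual reported is the objective at the clamped value.
#' With `config$integration = "full"` the sum instead runs over every sample
#' in the quality window on all four channels.
#'
#' @param mixed the mixed [Chromatogram].
#' @param w1,w2 [WarpedTrace]s of the references.
#' @param scale the [AmplitudeScale].
#' @param informative columns from [informativeColumns()].
#' @param config a [qsangerConfig()].
#' @return a [RatioEstimate]; its `diagnostics$perColumnOmega` gives the
#'   unclamped per-column estimates for inspection.
#' @export
estimateOmega <- function(mixed, w1, w2, scale, informative,
                          config = qsangerConfig()) {
    if (nrow(informative) < 1L) stop("no informative columns")
    des <- omegaDesign(mixed, w1, w2, scale, informative, config)
    if (length(des$bM) == 0L)
        stop("no usable samples on the anchor span")
    om <- closedFormOmega(des$bM, des$f1, des$f2)
    if (is.na(om))
        stop("degenerate contrast: references indistinguishable on support")
    omC <- min(1, max(0, om))
    resid <- sum((des$bM - omC * des$f1 - (1 - omC) * des$f2)^2)
    perCol <- vapply(unique(des$colId[des$colId > 0L]), function(k) {
        i <- des$colId == k
        closedFormOmega(des$bM[i], des$f1[i], des$f2[i])
    }, numeric(1))
    meta <- S4Vectors::metadata(informative)
    nm <- meta$nMismatch
    win <- meta$window
    new("RatioEstimate", omega = omC, residual = resid,
        nInformative = nrow(informative),
        nMismatch = if (is.null(nm)) 0L else as.integer(nm),
        window = if (is.null(win)) c(NA_integer_, NA_integer_) else win,
        diagnostics = list(unclampedOmega = om, perColumnOmega = perCol,
                           nSamples = length(des$bM)))
}

withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Quantify a two-variant mixture end-to-end
#'
#' Composes the full pipeline: trim all three reads to the quality window,
#' call peaks, globally align the mixed read against both references, pick
#' anchor points, warp the references into the mixed time frame, compute
#' amplitude gains, select informative divergent columns and solve the
#' least-squares mixture model. Any stage failure is re-raised with the
#' stage name prefixed.
#'
#' @param mixed,ref1,ref2 [Chromatogram]s: the mixed read and the two
#'   single-variant reference reads.
#' @param config a [qsangerConfig()].
#' @return a [RatioEstimate]; `omega()` is the estimated fraction of the
#'   `ref1` variant. Diagnostics carry the anchor count, total alignment
#'   score and a configuration echo.
#' @examples
#' p <- divergentPair(150, 10, seed = 7)
#' trio <- simulateMixture(p$seq1, p$seq2, omega = 0.3, simSpec(seed = 7))
#' est <- quantifyMixture(trio$mixed, trio$ref1, trio$ref2,
#'                        config = qsangerConfig(trimFirst = 5,
#'                                               windowEnd = 140))
#' omega(est)
#' @export
quantifyMixture <- function(mixed, ref1, ref2, config = qsangerConfig()) {
    tM <- withStage("trim", trimRead(mixed, config$trimFirst, config$trimLast))
    t1 <- withStage("trim", trimRead(ref1, config$trimFirst, config$trimLast))
    t2 <- withStage("trim", trimRead(ref2, config$trimFirst, config$trimLast))
    cols <- withStage("align", alignTraces(tM, t1, t2, config))
    anchors <- withStage("anchors",
        selectAnchors(cols, tM, t1, t2, config$purityThreshold,
                      config$minAnchors))
    w1 <- withStage("warp", timeStretch(t1, anchors, "p1"))
    w2 <- withStage("warp", timeStretch(t2, anchors, "p2"))
    scale <- withStage("gains", amplitudeScale(tM, w1, w2, anchors))
    informative <- withStage("informative",
        informativeColumns(cols, c(config$windowStart, config$windowEnd)))
    est <- withStage("estimate",
        estimateOmega(tM, w1, w2, scale, informative, config))
    est@diagnostics$nAnchors <- nrow(anchors)
    est@diagnostics$alignmentScore <- S4Vectors::metadata(cols)$totalScore
    est@diagnostics$config <- unclass(config)
    est
}
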