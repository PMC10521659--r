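mkAnchors <- function(tM, tP1, tP2 = tP1, base = "G") {
    S4Vectors::DataFrame(mIndex = seq_along(tM), p1Index = seq_along(tP1),
                         p2Index = seq_along(tP2), base = base,
                         tM = as.integer(tM), tP1 = as.integer(tP1),
                         tP2 = as.integer(tP2))
}

sineChrom <- function(T, period = 40) {
    ch <- matrix(0, T, 4, dimnames = list(NULL, c("G", "A", "T", "C")))
    ch[, "G"] <- 1000 + 500 * sin(2 * pi * seq_len(T) / period)
    Chromatogram(ch, peakTimes = c(10L, T - 10L), basecalls = "GG")
}

test_that("identity anchors reproduce the reference on the span", {
    ref <- sineChrom(300)
    w <- timeStretch(ref, mkAnchors(c(20, 150, 280), c(20, 150, 280)), "p1")
    expect_equal(w@offset, 20L)
    expect_equal(channels(w)[, "G"], channels(ref)[20:280, "G"])
})

test_that("segment warping follows the anchor-interval linear map", {
    ref <- sineChrom(400)
    # mixed 100 -> ref 110, mixed 200 -> ref 230; query 150 samples ref 170
    w <- timeStretch(ref, mkAnchors(c(100, 200), c(110, 230)), "p1")
    expect_equal(channels(w)[150 - 100 + 1, "G"], channels(ref)[170, "G"])
    # anchors are exact
    expect_equal(channels(w)[1, "G"], channels(ref)[110, "G"])
    expect_equal(channels(w)[101, "G"], channels(ref)[230, "G"])
})

test_that("a uniform 2x stretch matches the analytic resampling", {
    period <- 60
    ref <- sineChrom(800, period)
    w <- timeStretch(ref, mkAnchors(c(50, 350), c(100, 700)), "p1")
    tt <- 50:350
    refTime <- 100 + (tt - 50) * 2
    analytic <- 1000 + 500 * sin(2 * pi * refTime / period)
    # linear interpolation on an integer-mapped grid: agreement within 1e-6
    # of the amplitude scale
    expect_lt(max(abs(channels(w)[, "G"] - analytic)), 1e-6 * 1500)
})

test_that("non-monotone anchors are rejected", {
    ref <- sineChrom(300)
    expect_error(timeStretch(ref, mkAnchors(c(100, 200), c(230, 110)), "p1"),
                 "increasing")
    expect_error(timeStretch(ref, mkAnchors(100, 110), "p1"),
                 "at least 2 anchors")
})

test_that("gains interpolate anchor amplitude ratios linearly", {
    T <- 300L
    mixedCh <- matrix(0, T, 4, dimnames = list(NULL, c("G", "A", "T", "C")))
    refCh <- mixedCh
    # anchors at 100 and 200 with mixed/ref ratios 0.5 and 0.7
    refCh[100, "G"] <- 1000; refCh[200, "G"] <- 1000
    refCh[, "G"] <- pmax(refCh[, "G"], 1)   # nonzero between anchors
    mixedCh[100, "G"] <- 500; mixedCh[200, "G"] <- 700
    mixed <- Chromatogram(mixedCh, peakTimes = c(100L, 200L), basecalls = "GG")
    ref <- Chromatogram(refCh, peakTimes = c(100L, 200L), basecalls = "GG")
    anchors <- mkAnchors(c(100, 200), c(100, 200))
    w <- timeStretch(ref, anchors, "p1")
    sc <- amplitudeScale(mixed, w, w, anchors)
    expect_equal(qsanger:::lambdaAt(sc, 1L, 100L), 0.5)
    expect_equal(qsanger:::lambdaAt(sc, 1L, 200L), 0.7)
    expect_equal(qsanger:::lambdaAt(sc, 1L, 150L), 0.6)  # midpoint gain
})

test_that("gain curves track a decay-rate mismatch between runs", {
    seq <- strrep("GATTACAGGC", 15)
    spM <- simSpec(noiseSd = 0, decay = 2e-3, seed = 31)
    spR <- simSpec(noiseSd = 0, decay = 1e-3, seed = 31)
    m <- simulateTrace(seq, spM)
    r <- simulateTrace(seq, spR)
    cols <- alignTraces(m, r, r)
    anchors <- selectAnchors(cols, m, r, r)
    w <- timeStretch(r, anchors, "p1")
    sc <- amplitudeScale(m, w, w, anchors)
    # analytic gain at base k: exp(-(2e-3 - 1e-3) * (k - 1))
    k <- anchors$p1Index
    analytic <- exp(-1e-3 * (k - 1))
    got <- qsanger:::lambdaAt(sc, 1L, anchors$tM)
    expect_lt(max(abs(got - analytic) / analytic), 0.02)
})

test_that("all-zero denominators across anchors are an error", {
    T <- 300L
    z <- matrix(0, T, 4, dimnames = list(NULL, c("G", "A", "T", "C")))
    mixed <- Chromatogram(z + 1, peakTimes = c(100L, 200L), basecalls = "GG")
    ref <- Chromatogram(z, peakTimes = c(100L, 200L), basecalls = "GG")
    anchors <- mkAnchors(c(100, 200), c(100, 200))
    w <- timeStretch(ref, anchors, "p1")
    expect_error(amplitudeScale(mixed, w, w, anchors), "no usable gain")
})
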