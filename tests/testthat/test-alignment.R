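test_that("three-way column scores follow the peak-aware scheme", {
    expect_equal(scoreColumn("G", NA, "G", "G"), 1)
    expect_equal(scoreColumn("G", NA, "G", "T"), 2)
    expect_equal(scoreColumn("G", "T", "G", "T"), 0.85)
    expect_equal(scoreColumn("T", "G", "G", "T"), 0.85)  # either assignment
    expect_equal(scoreColumn("G", "T", "G", "C"), 0.75)
    expect_equal(scoreColumn("A", NA, "G", "T"), 0)
    expect_equal(scoreColumn("A", "C", "G", "T"), 0)
})

simpleTriple <- function(seqM, seq1, seq2, seed = 1) {
    sp <- simSpec(noiseSd = 0, seed = seed)
    list(m = simulateTrace(seqM, sp), p1 = simulateTrace(seq1, sp),
         p2 = simulateTrace(seq2, sp))
}

test_that("identical single-peak reads align gap-free with score = length", {
    s <- strrep("GATTC", 6)
    tr <- simpleTriple(s, s, s)
    cols <- alignTraces(tr$m, tr$p1, tr$p2)
    expect_equal(nrow(cols), 30L)
    expect_true(all(!is.na(cols$mIndex) & !is.na(cols$p1Index) &
                    !is.na(cols$p2Index)))
    expect_equal(S4Vectors::metadata(cols)$totalScore, 30)
    expect_equal(cols$score, rep(1, 30))
})

test_that("a deletion in the mixed read produces one gap column and costs the gap penalty", {
    s <- "GATTCAGGCTAACGGTTACGTAGCATCGAC"
    sDel <- paste0(substr(s, 1, 14), substr(s, 16, 30))
    tr <- simpleTriple(sDel, s, s)
    cols <- alignTraces(tr$m, tr$p1, tr$p2)
    gap1 <- which(is.na(cols$mIndex) & !is.na(cols$p1Index))
    gap2 <- which(is.na(cols$mIndex) & !is.na(cols$p2Index))
    expect_equal(length(gap1), 1L)   # exactly one gap column against P1
    expect_equal(length(gap2), 1L)
    expect_equal(cols$score[gap1], -2)
    # 29 matching columns plus one -2 gap column per reference
    expect_equal(S4Vectors::metadata(cols)$totalScore, 29 + 2 * (-2))
})

test_that("a two-peak mixed column over divergent references scores 0.85", {
    p <- divergentPair(40, 1, seed = 8)
    sp <- simSpec(noiseSd = 0, seed = 8)
    trio <- simulateMixture(p$seq1, p$seq2, 0.5, sp, spec1 = sp, spec2 = sp)
    cols <- alignTraces(trio$mixed, trio$ref1, trio$ref2)
    div <- which(!is.na(cols$p1Base) & !is.na(cols$p2Base) &
                 cols$p1Base != cols$p2Base)
    expect_equal(length(div), 1L)
    expect_equal(cols$score[div], 0.85)
})

test_that("the aligner reproduces an exhaustive-recursion oracle on short pairs", {
    S <- qsanger:::pairSubMatrix()
    ext <- rownames(S)
    plain <- colnames(S)
    set.seed(424)
    for (rep in 1:220) {
        n <- sample(1:8, 1); m <- sample(1:8, 1)
        a <- sample(ext, n, replace = TRUE)
        b <- sample(plain, m, replace = TRUE)
        got <- qsanger:::nw_align(match(a, ext), match(b, plain), S, -2)$score
        want <- oracleAlignScore(a, b, S, -2)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("anchor selection enforces identity, purity and the minimum count", {
    s <- "GATTCA"
    tr <- simpleTriple(s, s, s)
    cols <- alignTraces(tr$m, tr$p1, tr$p2)
    anchors <- selectAnchors(cols, tr$m, tr$p1, tr$p2)
    expect_equal(nrow(anchors), 6L)
    expect_true(all(diff(anchors$tM) > 0))
    expect_true(all(diff(anchors$tP1) > 0))
    expect_true(all(diff(anchors$tP2) > 0))
    # deterministic under re-running
    expect_identical(as.data.frame(anchors),
                     as.data.frame(selectAnchors(cols, tr$m, tr$p1, tr$p2)))

    s4 <- "GATT"
    tr4 <- simpleTriple(s4, s4, s4)
    # alignment itself requires 5 bases; 4 identical columns cannot anchor
    expect_error(alignTraces(tr4$m, tr4$p1, tr4$p2), "fewer than 5")

    # 6 columns but only 4 usable anchors (two impure in P1) -> hard error
    dirty <- channels(tr$p1)
    t2 <- peakTimes(tr$p1)[2]; t4 <- peakTimes(tr$p1)[4]
    dirty[t2, "C"] <- 0.03 * sum(dirty[t2, ]) / (1 - 0.03)
    dirty[t4, "C"] <- 0.03 * sum(dirty[t4, ]) / (1 - 0.03)
    p1dirty <- Chromatogram(dirty, peakTimes = peakTimes(tr$p1),
                            basecalls = basecalls(tr$p1))
    expect_error(selectAnchors(cols, tr$m, p1dirty, tr$p2),
                 "insufficient anchor points")
})

test_that("a 3% secondary channel in one reference disqualifies the anchor", {
    s <- "GATTCAG"
    tr <- simpleTriple(s, s, s)
    dirty <- channels(tr$p1)
    t3 <- peakTimes(tr$p1)[3]
    dirty[t3, "C"] <- 0.03 * sum(dirty[t3, ]) / (1 - 0.03)  # 3% of new sum
    p1dirty <- Chromatogram(dirty, peakTimes = peakTimes(tr$p1),
                            basecalls = basecalls(tr$p1))
    cols <- alignTraces(tr$m, p1dirty, tr$p2)
    anchors <- selectAnchors(cols, tr$m, p1dirty, tr$p2)
    expect_equal(nrow(anchors), 6L)
    expect_false(3L %in% anchors$p1Index)
})
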