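test_that("a single noise-free base yields one clean Gaussian peak", {
    cg <- simulateTrace("G", simSpec(noiseSd = 0, seed = 1))
    ch <- channels(cg)
    expect_true(all(ch[, c("A", "T", "C")] == 0))
    expect_gt(max(ch[, "G"]), 0)
    expect_equal(which.max(ch[, "G"]), peakTimes(cg))
    expect_equal(max(ch[, "G"]), 5000, tolerance = 0.03)
})

test_that("simulation is deterministic under a fixed seed", {
    sp <- simSpec(seed = 77, warpStretch = 0.05)
    expect_chrom_equal(simulateTrace("GATTACA", sp),
                       simulateTrace("GATTACA", sp))
    # different seeds give different layouts (independent runs)
    a <- simulateTrace("GATTACA", simSpec(seed = 1, warpStretch = 0.05))
    b <- simulateTrace("GATTACA", simSpec(seed = 2, warpStretch = 0.05))
    expect_false(identical(peakTimes(a), peakTimes(b)))
})

test_that("peak calling on a noise-free 100-mer recovers the input sequence", {
    p <- divergentPair(100, 5, seed = 13)
    cg <- simulateTrace(p$seq1, simSpec(noiseSd = 0, seed = 13))
    calls <- callPeaks(cg)
    expect_identical(paste(calls$primaryBase, collapse = ""), p$seq1)
    expect_true(all(is.na(calls$secondaryBase)))
})

test_that("the pre-noise mixed signal is the exact convex combination", {
    p <- divergentPair(60, 8, seed = 3)
    sp <- simSpec(noiseSd = 0, seed = 3)
    trio <- simulateMixture(p$seq1, p$seq2, 0.3, sp, spec1 = sp, spec2 = sp)
    pure1 <- simulateTrace(p$seq1, sp)
    pure2 <- simulateTrace(p$seq2, sp)
    expect_equal(channels(trio$mixed),
                 0.3 * channels(pure1) + 0.7 * channels(pure2))
    # omega = 1 degenerates to the pure variant-1 trace
    trio1 <- simulateMixture(p$seq1, p$seq2, 1, sp, spec1 = sp, spec2 = sp)
    expect_chrom_equal(trio1$mixed, pure1)
})

test_that("simulation inputs are validated", {
    expect_error(simSpec(peakSpacing = 5, peakWidth = 2), "resolvable")
    expect_error(simSpec(decay = -1), "non-negative")
    expect_error(simulateTrace("GANC", simSpec()), "only G, A, T, C")
    expect_error(simulateMixture("GATC", "GAT", 0.5, simSpec()),
                 "equal length")
    expect_error(simulateMixture("GATC", "GATT", 1.5, simSpec()),
                 "\\[0, 1\\]")
})

test_that("crosstalk leaks channels as specified", {
    ct <- diag(4); ct[1, 2] <- 0.05   # 5% of G bleeds into A
    cg <- simulateTrace("GGG", simSpec(noiseSd = 0, crosstalk = ct, seed = 4))
    ch <- channels(cg)
    expect_equal(ch[, "A"], 0.05 * ch[, "G"])
})

test_that("recovery experiment reports errors per row and demands contrast", {
    expect_error(recoveryExperiment(c(0.5, 0.5), reps = 1, seqLength = 80,
                                    nDivergent = 5,
                                    spec = simSpec(noiseSd = 0),
                                    config = qsangerConfig(trimFirst = 5,
                                                           windowEnd = 75),
                                    seed = 2),
                 "degenerate design")
})

test_that("a perfect two-point design recovers with R^2 = 1", {
    # lm warns about an essentially perfect fit: that is the point here
    rec <- suppressWarnings(recoveryExperiment(c(0, 1), reps = 2,
                              seqLength = 120,
                              nDivergent = 8,
                              spec = simSpec(noiseSd = 0),
                              config = qsangerConfig(trimFirst = 10,
                                                     windowEnd = 110),
                              independentRefs = FALSE, seed = 9))
    expect_equal(rec$r.squared, 1, tolerance = 1e-9)
    expect_true(all(is.na(rec$table$error)))
})

test_that("more divergent sites between anchors sharpen the estimate", {
    # synthetic informativeness study: with noise, recovery error with a
    # single divergent base is stochastically wider than with four
    errFor <- function(nDiv, seeds) {
        vapply(seeds, function(s) {
            p <- divergentPair(120, nDiv, seed = s)
            trio <- simulateMixture(p$seq1, p$seq2, 0.5,
                                    simSpec(noiseSd = 150, seed = s))
            est <- quantifyMixture(trio$mixed, trio$ref1, trio$ref2,
                                   qsangerConfig(trimFirst = 10,
                                                 windowStart = 5,
                                                 windowEnd = 110))
            abs(omega(est) - 0.5)
        }, numeric(1))
    }
    seeds <- 101:115
    e1 <- errFor(1, seeds)
    e4 <- errFor(4, seeds)
    expect_lt(wilcox.test(e4, e1, alternative = "less")$p.value, 0.1)
})
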