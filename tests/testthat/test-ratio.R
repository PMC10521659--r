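test_that("informative columns respect the window, divergence and consistency rules", {
    trio <- exactTrio(0.5, seed = 14, len = 200, nDiv = 12)
    cfg <- qsangerConfig()
    tM <- trimRead(trio$mixed); t1 <- trimRead(trio$ref1)
    t2 <- trimRead(trio$ref2)
    cols <- alignTraces(tM, t1, t2)
    inf <- informativeColumns(cols, c(20, 600))
    expect_true(all(inf$p1Base != inf$p2Base))
    expect_true(all(inf$mIndex >= 20 & inf$mIndex <= 600))
    expect_gte(nrow(inf), 1)

    # shrinking the window drops out-of-window divergent columns
    narrow <- informativeColumns(cols, c(20, min(inf$mIndex)))
    expect_lt(nrow(narrow), nrow(inf))

    # identical references have no divergent columns at all
    colsId <- alignTraces(tM, t1, t1)
    expect_error(informativeColumns(colsId, c(20, 600)),
                 "do not diverge in window")
})

test_that("mismatch columns are counted but never fitted", {
    # refs diverge at positions 4 (G vs T) and 6 (G vs A); the mixed read
    # peaks at A at position 4 (matches neither ref: mismatch) and shows a
    # proper G+A double peak at position 6 (informative)
    n <- 8
    base <- matrix(rep(c(5000, 0, 0, 0), n), n, 4, byrow = TRUE)
    ref1cols <- base
    ref2cols <- base; ref2cols[4, ] <- c(0, 0, 5000, 0)
    ref2cols[6, ] <- c(0, 5000, 0, 0)
    mixCols <- base
    mixCols[4, ] <- c(0, 5000, 0, 0)
    mixCols[6, ] <- c(2500, 2500, 0, 0)
    cols <- alignTraces(columnChrom(mixCols), columnChrom(ref1cols),
                        columnChrom(ref2cols))
    inf <- informativeColumns(cols, c(1, 8))
    expect_equal(nrow(inf), 1L)
    expect_equal(inf$mIndex, 6L)
    expect_equal(S4Vectors::metadata(inf)$nMismatch, 1L)
})

test_that("the closed form matches pure-variant and symmetric-mixture limits", {
    trio1 <- exactTrio(1, seed = 5)
    est1 <- quantifyMixture(trio1$mixed, trio1$ref1, trio1$ref2)
    expect_equal(omega(est1), 1, tolerance = 1e-3)
    expect_lt(residualError(est1) / sum(channels(trio1$mixed)^2), 1e-12)

    trio <- exactTrio(0.5, seed = 6)
    est5 <- quantifyMixture(trio$mixed, trio$ref1, trio$ref2)
    expect_equal(omega(est5), 0.5, tolerance = 1e-3)
})

test_that("the closed form equals the numeric minimizer on random instances", {
    set.seed(99)
    for (i in 1:25) {
        f1 <- runif(50, 0, 4000)
        f2 <- runif(50, 0, 4000)
        u <- runif(1, 0.1, 0.9)
        bM <- u * f1 + (1 - u) * f2 + rnorm(50, 0, 20)
        got <- qsanger:::closedFormOmega(bM, f1, f2)
        expect_equal(got, oracleOmega(bM, f1, f2), tolerance = 1e-6)
    }
})

test_that("quantify recovers a noise-free, mildly warped 0.3 mixture within 0.01", {
    p <- divergentPair(300, 18, seed = 17)
    trio <- simulateMixture(p$seq1, p$seq2, 0.3,
                            simSpec(noiseSd = 0, seed = 17,
                                    warpStretch = 0.04))
    est <- quantifyMixture(trio$mixed, trio$ref1, trio$ref2)
    expect_lt(abs(omega(est) - 0.3), 0.01)
    expect_gte(est@diagnostics$nAnchors, 5)
})

test_that("identical reference sequences abort with a stage-named error", {
    p <- divergentPair(150, 8, seed = 23)
    sp <- simSpec(noiseSd = 0, seed = 23)
    trio <- simulateMixture(p$seq1, p$seq1, 0.5, sp)
    expect_error(quantifyMixture(trio$mixed, trio$ref1, trio$ref2),
                 "\\[informative\\].*do not diverge in window")
})

test_that("degenerate contrast on the support is detected", {
    expect_true(is.na(qsanger:::closedFormOmega(runif(10), rep(5, 10),
                                                rep(5, 10))))
})

test_that("full-span integration agrees with informative-support integration", {
    trio <- exactTrio(0.25, seed = 41)
    estI <- quantifyMixture(trio$mixed, trio$ref1, trio$ref2)
    estF <- quantifyMixture(trio$mixed, trio$ref1, trio$ref2,
                            qsangerConfig(integration = "full"))
    expect_equal(omega(estI), 0.25, tolerance = 1e-3)
    expect_equal(omega(estF), 0.25, tolerance = 1e-2)
})

test_that("the JSON run report echoes the estimate and configuration", {
    trio <- exactTrio(0.75, seed = 51)
    est <- quantifyMixture(trio$mixed, trio$ref1, trio$ref2)
    js <- jsonlite::fromJSON(ratioReport(est))
    expect_equal(js$omega, omega(est))
    expect_equal(js$n_informative, nInformative(est))
    expect_equal(js$config$relThreshold, 0.014)
    expect_equal(js$window, c(20, 600))
})
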