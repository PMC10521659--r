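# Shared fixtures and independent oracles. Everything is generated in code;
# no binary files.

# a chromatogram whose peak columns are given explicitly: one row per called
# base, columns G, A, T, C; peaks placed 10 samples apart
columnChrom <- function(cols, basecalls = NULL) {
    n <- nrow(cols)
    T <- 10L * n + 10L
    ch <- matrix(0, T, 4, dimnames = list(NULL, c("G", "A", "T", "C")))
    pt <- 10L * seq_len(n)
    for (k in seq_len(n)) ch[pt[k], ] <- as.numeric(cols[k, ])
    if (is.null(basecalls))
        basecalls <- paste(c("G", "A", "T", "C")[max.col(cols,
            ties.method = "first")], collapse = "")
    Chromatogram(ch, peakTimes = pt, basecalls = basecalls, sampleId = "toy")
}

# independent global-alignment oracle: top-down memoized recursion over the
# same substitution function, kept separate from the package's DP
oracleAlignScore <- function(aChars, bChars, S, gap) {
    n <- length(aChars); m <- length(bChars)
    memo <- matrix(NA_real_, n + 1L, m + 1L)
    rec <- function(i, j) {
        if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
        v <- if (i == 0L && j == 0L) 0
        else {
            cand <- numeric(0)
            if (i > 0L && j > 0L)
                cand <- c(cand, rec(i - 1L, j - 1L) +
                              S[aChars[i], bChars[j]])
            if (i > 0L) cand <- c(cand, rec(i - 1L, j) + gap)
            if (j > 0L) cand <- c(cand, rec(i, j - 1L) + gap)
            max(cand)
        }
        memo[i + 1L, j + 1L] <<- v
        v
    }
    rec(n, m)
}

# numeric one-dimensional minimizer of the discretized mixture objective:
# coarse grid then local refinement, independent of the closed form
oracleOmega <- function(bM, f1, f2) {
    obj <- function(w) sum((bM - w * f1 - (1 - w) * f2)^2)
    grid <- seq(0, 1, by = 0.01)
    vals <- vapply(grid, obj, numeric(1))
    i <- which.min(vals)
    lo <- max(0, grid[i] - 0.02); hi <- min(1, grid[i] + 0.02)
    optimize(obj, c(lo, hi), tol = 1e-10)$minimum
}

# small noise-free identity-warp mixture triple: mixed and both references
# share one layout so the pipeline's exact-recovery limit applies
exactTrio <- function(omega, seed = 11, len = 200, nDiv = 12) {
    p <- divergentPair(len, nDiv, seed = seed)
    sp <- simSpec(noiseSd = 0, seed = seed)
    simulateMixture(p$seq1, p$seq2, omega, sp, spec1 = sp, spec2 = sp)
}

expect_chrom_equal <- function(a, b, tol = 0) {
    expect_equal(peakTimes(a), peakTimes(b))
    expect_equal(basecalls(a), basecalls(b))
    if (tol == 0) expect_equal(channels(a), channels(b))
    else expect_equal(channels(a), channels(b), tolerance = tol)
}
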