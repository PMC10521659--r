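#' @include chromatogram-class.R
NULL

#' SimSpec: configuration of the synthetic chromatogram generator
#'
#' Describes one simulated sequencing run. Each called base contributes a
#' Gaussian peak on its channel; peak amplitude decays exponentially along
#' the read; peak positions drift by per-base spacing jitter and an optional
#' monotone piecewise-linear time warp (emulating run-to-run migration
#' differences); dye crosstalk mixes the channels; truncated Gaussian noise
#' is added per sample.
#'
#' Defaults emulate an analyzed capillary trace: ~12 samples per base,
#' peak sd 2.4 samples (well-resolved: spacing > 4 sd), initial amplitude
#' 5000 units, decay 5e-4 per base (~40% amplitude loss over 1,000 bases),
#' noise sd 50 units (1% of the initial amplitude), no crosstalk, no warp.
#'
#' @slot peakSpacing mean samples between consecutive peaks.
#' @slot spacingJitter per-base sd of the spacing.
#' @slot peakWidth Gaussian peak sd, in samples.
#' @slot amp0 initial peak amplitude.
#' @slot decay per-base exponential amplitude decay rate.
#' @slot noiseSd additive per-sample channel noise sd (clipped at 0).
#' @slot crosstalk 4x4 leakage matrix (`crosstalk[i, j]` = fraction of
#'   channel `i` signal appearing on channel `j`; rows sum to at most 1.1).
#' @slot warpStretch if positive, a random monotone piecewise-linear warp
#'   with segment slopes in `[1 - warpStretch, 1 + warpStretch]` is drawn
#'   for the run.
#' @slot warpKnots explicit warp control points (2-column matrix, ideal and
#'   observed time, both strictly increasing) overriding `warpStretch`; or
#'   `NULL`.
#' @slot seed RNG seed for the run.
#'
#' @param peakSpacing,spacingJitter,peakWidth,amp0,decay,noiseSd,crosstalk,warpStretch,warpKnots,seed
#'   see slots.
#' @return `simSpec()` returns a validated `SimSpec`.
#' @examples
#' simSpec(noiseSd = 0, seed = 42)
#' @aliases SimSpec
#' @export simSpec
#' @exportClass SimSpec
setClass("SimSpec",
    representation(peakSpacing = "numeric", spacingJitter = "numeric",
                   peakWidth = "numeric", amp0 = "numeric",
                   decay = "numeric", noiseSd = "numeric",
                   crosstalk = "matrix", warpStretch = "numeric",
                   warpKnots = "ANY", seed = "integer"))

setValidity("SimSpec", function(object) {
    msg <- character(0)
    if (object@peakSpacing <= 4 * object@peakWidth)
        msg <- c(msg, "peakSpacing must exceed 4 * peakWidth (resolvable peaks)")
    if (object@decay < 0) msg <- c(msg, "decay must be non-negative")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
    if (object@amp0 <= 0) msg <- c(msg, "amp0 must be positive")
    ct <- object@crosstalk
    if (!all(dim(ct) == c(4L, 4L)) || any(ct < 0) ||
        any(rowSums(ct) > 1.1 + 1e-12))
        msg <- c(msg, "crosstalk must be a non-negative 4x4 matrix with row sums <= 1.1")
    if (object@warpStretch < 0 || object@warpStretch >= 1)
        msg <- c(msg, "warpStretch must lie in [0, 1)")
    wk <- object@warpKnots
    if (!is.null(wk)) {
        if (!is.matrix(wk) || ncol(wk) != 2L || nrow(wk) < 2L ||
            any(diff(wk[, 1]) <= 0) || any(diff(wk[, 2]) <= 0))
            msg <- c(msg, "warpKnots must be a 2-column strictly increasing matrix")
    }
    if (length(msg)) msg else TRUE
})

simSpec <- function(peakSpacing = 12, spacingJitter = 0.25, peakWidth = 2.4,
                    amp0 = 5000, decay = 5e-4, noiseSd = 50,
                    crosstalk = diag(4), warpStretch = 0, warpKnots = NULL,
                    seed = 1L) {
    new("SimSpec", peakSpacing = peakSpacing, spacingJitter = spacingJitter,
        peakWidth = peakWidth, amp0 = amp0, decay = decay, noiseSd = noiseSd,
        crosstalk = as.matrix(crosstalk), warpStretch = warpStretch,
        warpKnots = warpKnots, seed = as.integer(seed))
}

setMethod("show", "SimSpec", function(object) {
    cat("SimSpec: spacing", object@peakSpacing, "width", object@peakWidth,
        "amp0", object@amp0, "decay", object@decay, "noise",
        object@noiseSd, "warp",
        if (!is.null(object@warpKnots)) "explicit"
        else if (object@warpStretch > 0)
            paste0("random(", object@warpStretch, ")") else "identity",
        "seed", object@seed, "\n")
    invisible(NULL)
})

# derive a SimSpec differing only in seed (used for independent runs)
reseed <- function(spec, seed) {
    spec@seed <- as.integer(seed %% .Machine$integer.max)
    spec
}

withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

# peak centers for n bases: jittered spacings, then the run's monotone warp.
# Consumes RNG (spacing jitter, optionally warp slopes).
simLayout <- function(n, spec) {
    spac <- rnorm(n, spec@peakSpacing, spec@spacingJitter)
    spac <- pmax(spac, 4 * spec@peakWidth + 0.5)
    ideal <- spec@peakSpacing + cumsum(c(0, spac[-1]))
    knots <- spec@warpKnots
    if (is.null(knots) && spec@warpStretch > 0) {
        nSeg <- 6L
        x <- seq(0, max(ideal) + 4 * spec@peakSpacing, length.out = nSeg + 1L)
        slopes <- runif(nSeg, 1 - spec@warpStretch, 1 + spec@warpStretch)
        y <- cumsum(c(0, slopes * diff(x)))
        knots <- cbind(x, y)
    }
    centers <- if (is.null(knots)) ideal
               else approx(knots[, 1], knots[, 2], xout = ideal, rule = 2)$y
    centers + 1  # keep first peak away from sample 1
}

# noise-free 4-channel signal of one sequence on given peak centers
gaussSignal <- function(seqChars, centers, T, spec) {
    sig <- matrix(0, T, 4, dimnames = list(NULL, BASES))
    w <- spec@peakWidth
    amps <- spec@amp0 * exp(-spec@decay * (seq_along(seqChars) - 1))
    for (k in seq_along(seqChars)) {
        c0 <- centers[k]
        tt <- max(1L, floor(c0 - 5 * w)):min(T, ceiling(c0 + 5 * w))
        sig[tt, seqChars[k]] <- sig[tt, seqChars[k]] +
            amps[k] * exp(-(tt - c0)^2 / (2 * w^2))
    }
    sig
}

checkSeq <- function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    if (length(ch) < 1L || length(ch) > 1500L)
        stop("sequence length must be in 1..1500")
    if (!all(ch %in% BASES)) stop("sequence must contain only G, A, T, C")
    ch
}

finishTrace <- function(sig, centers, seqStr, spec, sampleId) {
    sig <- sig %*% spec@crosstalk
    colnames(sig) <- BASES
    if (spec@noiseSd > 0)
        sig <- sig + matrix(rnorm(length(sig), 0, spec@noiseSd), nrow(sig))
    sig[sig < 0] <- 0
    pt <- as.integer(round(centers))
    bump <- which(diff(pt) <= 0L)
    while (length(bump)) {          # rounding collisions: nudge forward
        pt[bump + 1L] <- pt[bump] + 1L
        bump <- which(diff(pt) <= 0L)
    }
    Chromatogram(sig, peakTimes = pt, basecalls = seqStr, sampleId = sampleId)
}

#' Simulate a single-variant chromatogram
#'
#' Generates a 4-channel trace for one sequence under a [simSpec()]:
#' Gaussian peaks with exponential amplitude decay, jittered spacing, the
#' run's monotone time warp, dye crosstalk and truncated Gaussian noise.
#' Peak times are set to the (rounded) warped peak centers and base calls to
#' the input sequence. Deterministic for a fixed `spec@seed`.
#'
#' @param seq a plain `G/A/T/C` character string, at most 1,500 bases.
#' @param spec a [simSpec()].
#' @param sampleId identifier for the resulting trace.
#' @return a [Chromatogram].
#' @examples
#' cg <- simulateTrace("GATTACA", simSpec(noiseSd = 0, seed = 3))
#' basecalls(cg)
#' @export
simulateTrace <- function(seq, spec, sampleId = "sim") {
    validObject(spec)
    ch <- checkSeq(seq)
    withSeed(spec@seed, {
        centers <- simLayout(length(ch), spec)
        T <- as.integer(ceiling(max(centers) + 3 * spec@peakSpacing))
        sig <- gaussSignal(ch, centers, T, spec)
        finishTrace(sig, centers, paste(ch, collapse = ""), spec, sampleId)
    })
}

#' Simulate a mixed read plus its two reference reads
#'
#' The mixed trace models a single sequencing reaction over a two-variant
#' template pool: both variants share the run's peak positions and warp, and
#' the pre-noise signal is the exact convex combination
#' `omega * signal(seq1) + (1 - omega) * signal(seq2)`. The reference reads
#' are independent runs (their own seeds, hence their own jitter, warps and
#' noise), by default derived from `spec` by reseeding.
#'
#' @param seq1,seq2 equal-length plain base sequences (gap-free alignment is
#'   assumed).
#' @param omega true fraction of `seq1` in the mixture, in `[0, 1]`.
#' @param spec the mixed run's [simSpec()].
#' @param spec1,spec2 reference run specs; default: `spec` reseeded.
#' @return a list with [Chromatogram] elements `mixed`, `ref1`, `ref2` and
#'   the scalar `omega`.
#' @examples
#' p <- divergentPair(60, 6, seed = 2)
#' trio <- simulateMixture(p$seq1, p$seq2, 0.3, simSpec(seed = 2))
#' trio$mixed
#' @export
simulateMixture <- function(seq1, seq2, omega, spec,
                            spec1 = reseed(spec, spec@seed + 1009L),
                            spec2 = reseed(spec, spec@seed + 2003L)) {
    if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]")
    ch1 <- checkSeq(seq1); ch2 <- checkSeq(seq2)
    if (length(ch1) != length(ch2))
        stop("seq1 and seq2 must have equal length")
    validObject(spec)
    mixed <- withSeed(spec@seed, {
        centers <- simLayout(length(ch1), spec)
        T <- as.integer(ceiling(max(centers) + 3 * spec@peakSpacing))
        sig <- omega * gaussSignal(ch1, centers, T, spec) +
            (1 - omega) * gaussSignal(ch2, centers, T, spec)
        calls <- BASES[max.col(sig[as.integer(round(centers)), , drop = FALSE],
                               ties.method = "first")]
        finishTrace(sig, centers, paste(calls, collapse = ""), spec, "mixed")
    })
    list(mixed = mixed,
         ref1 = simulateTrace(seq1, spec1, "ref1"),
         ref2 = simulateTrace(seq2, spec2, "ref2"),
         omega = omega)
}

#' Generate a random pair of substitution-divergent sequences
#'
#' A random sequence and a copy with `nDivergent` substitutions placed in
#' the central 15-95% of the read, so that after default trimming the
#' divergent positions fall inside the quality window.
#'
#' @param length sequence length.
#' @param nDivergent number of substituted positions.
#' @param seed RNG seed.
#' @return list with `seq1`, `seq2`, and the substituted `positions`.
#' @export
divergentPair <- function(length, nDivergent, seed = 1L) {
    if (nDivergent >= length) stop("nDivergent must be below length")
    withSeed(seed, {
        s1 <- sample(BASES, length, replace = TRUE)
        lo <- max(1L, round(0.15 * length))
        hi <- max(lo + nDivergent, round(0.95 * length))
        pos <- sort(sample(lo:min(hi, length), nDivergent))
        s2 <- s1
        for (p in pos) s2[p] <- sample(setdiff(BASES, s1[p]), 1)
        list(seq1 = paste(s1, collapse = ""), seq2 = paste(s2, collapse = ""),
             positions = pos)
    })
}

#' Ratio-grid recovery experiment on synthetic mixtures
#'
#' Simulates the mixing-calibration design: for each requested true ratio
#' and replicate, generate a mixed read plus two reference reads
#' ([simulateMixture()], each run independently seeded), quantify the
#' mixture end-to-end ([quantifyMixture()]), and regress the estimates on
#' the truth. Failed quantifications are recorded per row, excluded from
#' the regression with a warning.
#'
#' @param ratios vector of true mixture fractions (needs at least two
#'   distinct values).
#' @param reps replicates per ratio.
#' @param seqLength,nDivergent geometry of the simulated template pair
#'   (see [divergentPair()]).
#' @param spec base [simSpec()]; each run is reseeded from `seed`.
#' @param config pipeline [qsangerConfig()].
#' @param independentRefs if `TRUE` (default) the reference reads of each
#'   run are independent sequencing runs with their own layouts; `FALSE`
#'   shares the mixed run's layout with the references — the idealized
#'   identity-warp regime in which recovery is exact.
#' @param seed master seed for the experiment.
#' @return an object of class `qsangerRecovery`: list with `table`
#'   (data.frame of `true`, `rep`, `estimated`, `error`), `r.squared`
#'   (squared Pearson correlation from the linear regression), and `fit`.
#' @examples
#' rec <- recoveryExperiment(c(0, 0.5, 1), reps = 1, seqLength = 150,
#'                           nDivergent = 10,
#'                           spec = simSpec(noiseSd = 0, seed = 5),
#'                           config = qsangerConfig(trimFirst = 5,
#'                                                  windowEnd = 140),
#'                           seed = 5)
#' rec$r.squared
#' @export
recoveryExperiment <- function(ratios, reps = 3, seqLength = 420,
                               nDivergent = 25, spec = simSpec(),
                               config = qsangerConfig(),
                               independentRefs = TRUE, seed = 1L) {
    if (reps < 1) stop("reps must be at least 1")
    pair <- divergentPair(seqLength, nDivergent, seed)
    grid <- expand.grid(rep = seq_len(reps), true = ratios)
    est <- rep(NA_real_, nrow(grid))
    err <- rep(NA_character_, nrow(grid))
    for (i in seq_len(nrow(grid))) {
        runSeed <- (as.integer(seed) + 7919L * i) %% 2147483647L
        runSpec <- reseed(spec, runSeed)
        trio <- if (independentRefs)
            simulateMixture(pair$seq1, pair$seq2, grid$true[i], runSpec)
        else
            simulateMixture(pair$seq1, pair$seq2, grid$true[i], runSpec,
                            spec1 = runSpec, spec2 = runSpec)
        res <- tryCatch(
            quantifyMixture(trio$mixed, trio$ref1, trio$ref2, config),
            error = function(e) e)
        if (inherits(res, "error")) err[i] <- conditionMessage(res)
        else est[i] <- omega(res)
    }
    tab <- data.frame(true = grid$true, rep = grid$rep, estimated = est,
                      error = err)
    ok <- !is.na(est)
    if (any(!ok))
        warning(sum(!ok), " of ", length(ok),
                " quantifications failed and were excluded")
    if (length(unique(tab$true[ok])) < 2L)
        stop("degenerate design: need at least two distinct true ratios ",
             "with successful estimates")
    fit <- lm(estimated ~ true, data = tab[ok, ])
    structure(list(table = tab, r.squared = summary(fit)$r.squared,
                   fit = fit), class = "qsangerRecovery")
}

#' @export
print.qsangerRecovery <- function(x, ...) {
    ok <- !is.na(x$table$estimated)
    cat("Synthetic ratio-grid recovery:", sum(ok), "of", nrow(x$table),
        "runs quantified\n")
    cat(sprintf("  R^2 (estimated vs true) = %.4f\n", x$r.squared))
    agg <- stats::aggregate(estimated ~ true, data = x$table[ok, ],
                            FUN = mean)
    for (i in seq_len(nrow(agg)))
        cat(sprintf("  true %.2f -> mean estimate %.3f\n",
                    agg$true[i], agg$estimated[i]))
    invisible(x)
}

#' Write a recovery table as TSV
#'
#' @param rec a `qsangerRecovery` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRecoveryTable <- function(rec, path) {
    write.table(rec$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
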