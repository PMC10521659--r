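#' @include chromatogram-class.R
NULL

# IUPAC two-base ambiguity codes; swap-invariant by construction
PAIR_CODE <- c("AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W",
               "GT" = "K", "AC" = "M")
CODE_PAIR <- local({
    p <- strsplit(names(PAIR_CODE), "")
    names(p) <- unname(PAIR_CODE)
    p
})

# argmax/argmax2 over one amplitude column with fixed G,A,T,C tie-break
rank2 <- function(amps) {
    ord <- order(-amps, seq_along(amps))   # ties: earlier base wins
    list(i1 = ord[1], i2 = ord[2])
}

#' Call primary and secondary peaks at each base position
#'
#' At each called peak time the channel with the largest amplitude is the
#' primary base. A secondary base is reported only when the second-largest
#' channel carries at least `relThreshold` of the summed 4-channel amplitude
#' at that time *and* at least `absThreshold` amplitude units; otherwise the
#' position is a single-peak call. Equal amplitudes are broken in fixed
#' channel order G, A, T, C.
#'
#' @param cg a [Chromatogram] with non-empty `peakTimes`.
#' @param relThreshold minimum fraction of the column sum for a secondary
#'   peak (default 0.014).
#' @param absThreshold minimum absolute amplitude for a secondary peak
#'   (default 50).
#' @return a [S4Vectors::DataFrame] with one row per position: `index`
#'   (1-based base position), `time`, `primaryBase`, `primaryAmp`,
#'   `secondaryBase` (`NA` when absent), `secondaryAmp` (0 when absent).
#' @examples
#' amp <- matrix(0, 5, 4, dimnames = list(NULL, c("G", "A", "T", "C")))
#' amp[3, ] <- c(7000, 140, 30, 30)
#' callPeaks(Chromatogram(amp, peakTimes = 3L, basecalls = "G"))
#' @export
callPeaks <- function(cg, relThreshold = 0.014, absThreshold = 50) {
    stopifnot(is(cg, "Chromatogram"))
    pt <- peakTimes(cg)
    ch <- channels(cg)
    n <- length(pt)
    primary <- character(n); secondary <- rep(NA_character_, n)
    amp1 <- numeric(n); amp2 <- numeric(n)
    for (k in seq_len(n)) {
        col <- ch[pt[k], ]
        r <- rank2(col)
        primary[k] <- BASES[r$i1]
        amp1[k] <- col[r$i1]
        a2 <- col[r$i2]
        if (a2 >= relThreshold * sum(col) && a2 >= absThreshold && a2 > 0) {
            secondary[k] <- BASES[r$i2]
            amp2[k] <- a2
        }
    }
    S4Vectors::DataFrame(index = seq_len(n), time = pt,
                         primaryBase = primary, primaryAmp = amp1,
                         secondaryBase = secondary, secondaryAmp = amp2)
}

#' Is a reference position pure (single-peak)?
#'
#' A position qualifies as pure when the second-largest channel at its peak
#' time is below `threshold` times the summed 4-channel amplitude. Pure
#' positions in *both* references are what anchor the time/amplitude
#' registration. An all-zero column is pure by convention (it carries no
#' secondary signal); such positions are excluded from anchoring elsewhere.
#'
#' @param cg a [Chromatogram].
#' @param K base position (1-based).
#' @param threshold purity fraction (default 0.028).
#' @return `TRUE` if the position is pure.
#' @export
purityOk <- function(cg, K, threshold = 0.028) {
    stopifnot(is(cg, "Chromatogram"))
    pt <- peakTimes(cg)
    if (K < 1L || K > length(pt)) stop("base position out of range: ", K)
    col <- channels(cg)[pt[K], ]
    s <- sum(col)
    if (s == 0) return(TRUE)
    r <- rank2(col)
    col[r$i2] < threshold * s
}

#' Encode peak calls with the extended (IUPAC two-base) alphabet
#'
#' Single-peak positions keep their plain base letter; two-peak positions
#' get the IUPAC ambiguity letter of the unordered `{primary, secondary}`
#' pair (`R`, `Y`, `S`, `W`, `K`, `M`), so a mixed read base-calls to one
#' letter per position regardless of which variant dominates.
#'
#' @param calls output of [callPeaks()].
#' @return a single character string over `G A T C R Y S W K M`.
#' @seealso [decodeExtended()]
#' @export
encodeExtended <- function(calls) {
    n <- nrow(calls)
    out <- character(n)
    for (k in seq_len(n)) {
        if (is.na(calls$secondaryBase[k])) {
            out[k] <- calls$primaryBase[k]
        } else {
            pair <- sort(c(calls$primaryBase[k], calls$secondaryBase[k]))
            out[k] <- PAIR_CODE[paste(pair, collapse = "")]
        }
    }
    paste(out, collapse = "")
}

#' Decode an extended-alphabet letter to its unordered base set
#'
#' @param letter a single letter in `G A T C R Y S W K M`.
#' @return character vector of 1 (plain) or 2 (ambiguity code) bases.
#' @export
decodeExtended <- function(letter) {
    if (letter %in% BASES) return(letter)
    p <- CODE_PAIR[[letter]]
    if (is.null(p)) stop("not an extended-alphabet letter: ", letter)
    p
}
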