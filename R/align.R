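#' @include peaks.R config.R
NULL

EXT_ALPHABET <- c(BASES, "R", "Y", "S", "W", "K", "M")

# pairwise substitution score of a mixed extended letter vs one plain
# reference base: the single-reference projection of the three-way column
# score (the 2 and 0.75 cases need both references and are recomputed on the
# merged columns)
pairSub <- function(mLetter, refBase) {
    peaks <- decodeExtended(mLetter)
    if (length(peaks) == 1L) {
        if (peaks == refBase) 1 else 0
    } else {
        if (refBase %in% peaks) 0.85 else 0
    }
}

pairSubMatrix <- function() {
    S <- matrix(0, length(EXT_ALPHABET), length(BASES),
                dimnames = list(EXT_ALPHABET, BASES))
    for (a in EXT_ALPHABET) for (b in BASES) S[a, b] <- pairSub(a, b)
    S
}

#' Three-way column score for the peak-aware alignment
#'
#' Scores one aligned column of (mixed, reference 1, reference 2) base
#' calls. A single mixed peak matching an identical-reference column scores
#' 1; a single peak matching exactly one of two *divergent* references
#' scores 2 (the most informative single-peak event); a two-peak mixed call
#' scores 0.85 when both peaks match the reference pair (in either
#' assignment) and 0.75 when exactly one does; anything else is a mismatch
#' scoring 0. Gap columns are scored by [alignTraces()].
#'
#' @param mPrimary primary mixed base (plain letter).
#' @param mSecondary secondary mixed base or `NA`.
#' @param p1,p2 reference base calls (plain letters).
#' @return the column score: one of 1, 2, 0.85, 0.75, 0.
#' @examples
#' scoreColumn("G", NA, "G", "T")   # single peak resolving divergent refs: 2
#' scoreColumn("G", "T", "G", "T")  # both peaks accounted for: 0.85
#' @export
scoreColumn <- function(mPrimary, mSecondary, p1, p2) {
    if (is.na(mSecondary)) {
        if (p1 == p2) {
            if (mPrimary == p1) 1 else 0
        } else {
            if (mPrimary == p1 || mPrimary == p2) 2 else 0
        }
    } else {
        hits <- sum(c(mPrimary, mSecondary) %in% c(p1, p2))
        if (hits == 2L) 0.85 else if (hits == 1L) 0.75 else 0
    }
}

# run one pairwise global alignment; returns for every mixed position the
# aligned reference position (NA = gap) plus reference-only insertions keyed
# by the mixed position they follow
alignPair <- function(mCodes, refCodes, S, gap) {
    r <- nw_align(mCodes, refCodes, S, gap)
    refFor <- rep(NA_integer_, length(mCodes))
    inserts <- integer(0)     # ref positions aligned to a mixed gap
    insertAfter <- integer(0) # mixed position each insert follows (0 = start)
    lastM <- 0L
    for (k in seq_along(r$ai)) {
        if (r$ai[k] > 0L && r$bi[k] > 0L) {
            refFor[r$ai[k]] <- r$bi[k]
            lastM <- r$ai[k]
        } else if (r$ai[k] > 0L) {
            lastM <- r$ai[k]
        } else {
            inserts <- c(inserts, r$bi[k])
            insertAfter <- c(insertAfter, lastM)
        }
    }
    list(refFor = refFor, inserts = inserts, insertAfter = insertAfter,
         score = r$score)
}

#' Align a mixed read against both reference reads
#'
#' Runs two peak-aware global alignments (mixed vs each reference) over the
#' extended-alphabet base calls, then merges them on mixed-read positions
#' into three-way columns. Each merged column is rescored with
#' [scoreColumn()]; a mixed base aligned to gaps in both references scores
#' `config$doubleGapScore`, and every other gap contributes
#' `config$gapPenalty`.
#'
#' @param mixed,ref1,ref2 trimmed [Chromatogram]s.
#' @param config a [qsangerConfig()].
#' @return a [S4Vectors::DataFrame] of columns: `mIndex`, `p1Index`,
#'   `p2Index` (`NA` = gap), `mPrimary`, `mSecondary`, `p1Base`, `p2Base`,
#'   `score`; metadata columns `totalScore`, `pairScore1`, `pairScore2`
#'   are attached via [S4Vectors::metadata()].
#' @export
alignTraces <- function(mixed, ref1, ref2, config = qsangerConfig()) {
    for (cg in list(mixed, ref1, ref2))
        if (length(peakTimes(cg)) < 5L)
            stop("read too short to align (fewer than 5 called bases)")
    mCalls <- callPeaks(mixed, config$relThreshold, config$absThreshold)
    c1 <- callPeaks(ref1, config$relThreshold, config$absThreshold)
    c2 <- callPeaks(ref2, config$relThreshold, config$absThreshold)
    mExt <- strsplit(encodeExtended(mCalls), "")[[1]]
    s1 <- c1$primaryBase
    s2 <- c2$primaryBase
    S <- pairSubMatrix()
    mCodes <- match(mExt, EXT_ALPHABET)
    a1 <- alignPair(mCodes, match(s1, EXT_ALPHABET), S, config$gapPenalty)
    a2 <- alignPair(mCodes, match(s2, EXT_ALPHABET), S, config$gapPenalty)

    n <- length(mCodes)
    rows <- vector("list", 0L)
    addRow <- function(mI, p1I, p2I) {
        rows[[length(rows) + 1L]] <<- list(mI, p1I, p2I)
    }
    for (pos in 0:n) {
        i1 <- which(a1$insertAfter == pos)
        for (k in i1) addRow(NA_integer_, a1$inserts[k], NA_integer_)
        i2 <- which(a2$insertAfter == pos)
        for (k in i2) addRow(NA_integer_, NA_integer_, a2$inserts[k])
        if (pos > 0L) addRow(pos, a1$refFor[pos], a2$refFor[pos])
    }
    mIndex <- vapply(rows, `[[`, 1L, 1)
    p1Index <- vapply(rows, `[[`, 1L, 2)
    p2Index <- vapply(rows, `[[`, 1L, 3)
    mPrimary <- ifelse(is.na(mIndex), NA_character_, mCalls$primaryBase[mIndex])
    mSecondary <- ifelse(is.na(mIndex), NA_character_,
                         mCalls$secondaryBase[mIndex])
    p1Base <- ifelse(is.na(p1Index), NA_character_, s1[p1Index])
    p2Base <- ifelse(is.na(p2Index), NA_character_, s2[p2Index])

    score <- numeric(length(rows))
    for (k in seq_along(rows)) {
        if (is.na(mIndex[k])) {
            score[k] <- config$gapPenalty
        } else if (is.na(p1Index[k]) && is.na(p2Index[k])) {
            score[k] <- config$doubleGapScore
        } else if (is.na(p1Index[k]) || is.na(p2Index[k])) {
            present <- if (is.na(p1Index[k])) p2Base[k] else p1Base[k]
            proj <- if (is.na(mSecondary[k])) {
                if (mPrimary[k] == present) 1 else 0
            } else {
                if (present %in% c(mPrimary[k], mSecondary[k])) 0.85 else 0
            }
            score[k] <- proj + config$gapPenalty
        } else {
            score[k] <- scoreColumn(mPrimary[k], mSecondary[k],
                                    p1Base[k], p2Base[k])
        }
    }
    out <- S4Vectors::DataFrame(mIndex = mIndex, p1Index = p1Index,
                                p2Index = p2Index, mPrimary = mPrimary,
                                mSecondary = mSecondary, p1Base = p1Base,
                                p2Base = p2Base, score = score)
    S4Vectors::metadata(out) <- list(totalScore = sum(score),
                                     pairScore1 = a1$score,
                                     pairScore2 = a2$score)
    out
}

#' Select anchor points from an alignment
#'
#' Anchors are gap-free columns where both references call the same base,
#' both reference positions are pure ([purityOk()]) and the mixed read shows
#' a single peak with non-zero signal — positions where all three traces
#' carry the same lone peak, safe for registering time and amplitude.
#' Columns that would break strict monotonicity of anchor times in any of
#' the three frames are dropped greedily (the earlier anchor is kept), since
#' the piecewise-linear warp requires monotone segments.
#'
#' @param cols alignment columns from [alignTraces()].
#' @param mixed,ref1,ref2 the same trimmed [Chromatogram]s.
#' @param purity reference purity threshold (default 0.028).
#' @param minAnchors minimum anchor count; fewer is a hard failure.
#' @return a [S4Vectors::DataFrame]: `mIndex`, `p1Index`, `p2Index`, `base`,
#'   `tM`, `tP1`, `tP2` (peak times in each read's own sample frame),
#'   strictly increasing in all three time columns.
#' @export
selectAnchors <- function(cols, mixed, ref1, ref2, purity = 0.028,
                          minAnchors = 5) {
    cand <- which(!is.na(cols$mIndex) & !is.na(cols$p1Index) &
                  !is.na(cols$p2Index) &
                  cols$p1Base == cols$p2Base &
                  is.na(cols$mSecondary))
    keepRows <- integer(0)
    ptM <- peakTimes(mixed); pt1 <- peakTimes(ref1); pt2 <- peakTimes(ref2)
    chM <- channels(mixed)
    lastT <- c(-Inf, -Inf, -Inf)
    for (r in cand) {
        mI <- cols$mIndex[r]; i1 <- cols$p1Index[r]; i2 <- cols$p2Index[r]
        if (sum(chM[ptM[mI], ]) <= 0) next           # no mixed signal at all
        if (!purityOk(ref1, i1, purity)) next
        if (!purityOk(ref2, i2, purity)) next
        tt <- c(ptM[mI], pt1[i1], pt2[i2])
        if (any(tt <= lastT)) next                   # monotonicity repair
        keepRows <- c(keepRows, r)
        lastT <- tt
    }
    if (length(keepRows) < minAnchors)
        stop("insufficient anchor points: found ", length(keepRows),
             ", need at least ", minAnchors)
    S4Vectors::DataFrame(
        mIndex = cols$mIndex[keepRows], p1Index = cols$p1Index[keepRows],
        p2Index = cols$p2Index[keepRows], base = cols$p1Base[keepRows],
        tM = ptM[cols$mIndex[keepRows]], tP1 = pt1[cols$p1Index[keepRows]],
        tP2 = pt2[cols$p2Index[keepRows]])
}

#' Dump an alignment column map as TSV
#'
#' Debug helper: writes the merged three-way column table produced by
#' [alignTraces()] to a tab-separated file.
#'
#' @param cols alignment columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeColumnMap <- function(cols, path) {
    write.table(as.data.frame(cols), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
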