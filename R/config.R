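#' Pipeline configuration with the method's published defaults
#'
#' All tunable constants of the quantification pipeline live here, never
#' hard-coded in the stage functions. Defaults: a secondary peak in the
#' mixed read must carry at least 1.4% of the column's total signal
#' (`relThreshold = 0.014`) and at least 50 amplitude units
#' (`absThreshold = 50`); a reference position is pure when its
#' second-largest channel is below 2.8% of the column sum
#' (`purityThreshold = 0.028`); reads are trimmed to called bases 20-1000;
#' only divergent positions with post-trim index in 20-600 contribute to the
#' estimate; at least 5 anchor points are required; gaps cost -2 per
#' position, a mixed base aligned against gaps in both references scores -1.
#'
#' @param relThreshold fraction of the 4-channel column sum a secondary peak
#'   must reach in the mixed read.
#' @param absThreshold absolute amplitude floor for a secondary peak.
#' @param purityThreshold secondary-signal fraction above which a reference
#'   position is no longer "pure" (unusable as an anchor).
#' @param trimFirst,trimLast 0-based base-call index window retained by
#'   [trimRead()].
#' @param windowStart,windowEnd post-trim base-call index window whose
#'   divergent positions feed the least-squares fit.
#' @param minAnchors minimum number of anchor points; fewer is a hard error.
#' @param gapPenalty per-position gap score in the global alignment.
#' @param doubleGapScore score of a mixed-read base aligned to gaps in both
#'   references.
#' @param integration `"informative"` sums the objective over fixed-width
#'   supports around divergent peaks (the default); `"full"` integrates over
#'   the whole window span.
#' @return a named list of class `qsangerConfig`.
#' @examples
#' cfg <- qsangerConfig(windowEnd = 400)
#' cfg$windowEnd
#' @export
qsangerConfig <- function(relThreshold = 0.014, absThreshold = 50,
                          purityThreshold = 0.028,
                          trimFirst = 20, trimLast = 1000,
                          windowStart = 20, windowEnd = 600,
                          minAnchors = 5, gapPenalty = -2,
                          doubleGapScore = -1,
                          integration = c("informative", "full")) {
    integration <- match.arg(integration)
    cfg <- list(relThreshold = relThreshold, absThreshold = absThreshold,
                purityThreshold = purityThreshold,
                trimFirst = as.integer(trimFirst),
                trimLast = as.integer(trimLast),
                windowStart = as.integer(windowStart),
                windowEnd = as.integer(windowEnd),
                minAnchors = as.integer(minAnchors),
                gapPenalty = gapPenalty, doubleGapScore = doubleGapScore,
                integration = integration)
    if (relThreshold <= 0 || absThreshold <= 0 || purityThreshold <= 0)
        stop("thresholds must be positive")
    if (cfg$trimFirst >= cfg$trimLast)
        stop("trimFirst must be smaller than trimLast")
    if (cfg$windowStart < 0 || cfg$windowEnd <= cfg$windowStart)
        stop("window bounds must satisfy 0 <= windowStart < windowEnd")
    if (cfg$windowEnd > cfg$trimLast - cfg$trimFirst)
        stop("window must lie inside the trimmed read")
    if (cfg$minAnchors < 2L)
        stop("minAnchors must be at least 2")
    if (cfg$gapPenalty >= 0 || cfg$doubleGapScore >= 0)
        stop("gap scores must be negative")
    structure(cfg, class = "qsangerConfig")
}

#' Read a configuration file
#'
#' Reads a JSON file of configuration overrides and merges it over the
#' defaults of [qsangerConfig()]. Unknown keys are an error.
#'
#' @param path path to a JSON object of configuration values.
#' @return a `qsangerConfig` list.
#' @export
readConfig <- function(path) {
    vals <- jsonlite::fromJSON(path)
    known <- names(formals(qsangerConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown configuration keys: ", paste(bad, collapse = ", "))
    do.call(qsangerConfig, vals)
}
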