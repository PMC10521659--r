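#' @include config.R
NULL

#' Calibration parameters for the fluorescence ratio estimator
#'
#' For the two-reporter validation system (variant 1 expresses mCherry,
#' variant 2 EGFP) the mixture fraction can be read from bulk red/green
#' fluorescence once two promoter-specific constants are known:
#' `lambda = R^P1 / G^P2` (red output of pure variant-1 cells over green
#' output of pure variant-2 cells) and `beta = G^P1 / R^P1` (green bleed of
#' pure variant-1 cells). `fluorParams()` builds a parameter set;
#' `paramsForPromoter()` looks up the calibrated values bundled for the
#' eight validation promoters.
#'
#' @param promoter promoter name.
#' @param lambda,beta dimensionless calibration ratios; `lambda > 0`,
#'   `beta >= 0`.
#' @return a `fluorParams` list with elements `promoter`, `lambda`, `beta`.
#' @examples
#' paramsForPromoter("pTet")
#' @export
fluorParams <- function(promoter, lambda, beta) {
    if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be positive")
    if (!is.numeric(beta) || beta < 0) stop("beta must be non-negative")
    structure(list(promoter = as.character(promoter), lambda = lambda,
                   beta = beta), class = "fluorParams")
}

fluorTable <- local({
    tab <- NULL
    function() {
        if (is.null(tab))
            tab <<- read.delim(system.file("extdata",
                                           "fluorescence_params.tsv",
                                           package = "qsanger"))
        tab
    }
})

#' @rdname fluorParams
#' @export
paramsForPromoter <- function(promoter) {
    tab <- fluorTable()
    i <- match(promoter, tab$promoter)
    if (is.na(i))
        stop("unknown promoter ", sQuote(promoter), "; bundled promoters: ",
             paste(tab$promoter, collapse = ", "))
    fluorParams(tab$promoter[i], tab$lambda[i], tab$beta[i])
}

#' Mixture fraction from red/green fluorescence
#'
#' Computes `omega = 1 / (1 + lambda * (G/R - beta))`, the fraction of the
#' red-reporter variant implied by bulk fluorescence of the mixed culture,
#' clamped to `[0, 1]` (noisy readings can push the raw value outside the
#' unit interval; clamped values are flagged with a warning). At
#' `G/R = beta` — a culture as green-poor as pure variant-1 cells — the
#' estimate is exactly 1; the raw value decreases strictly in `G/R`.
#'
#' @param red,green fluorescence readings (same arbitrary units);
#'   `red` must be positive. Vectorized.
#' @param params a `fluorParams` set, or a promoter name string to look up
#'   with [paramsForPromoter()].
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' p <- paramsForPromoter("pBAD")
#' omegaFromFluorescence(1000, 1000, p)
#' @export
omegaFromFluorescence <- function(red, green, params) {
    if (is.character(params)) params <- paramsForPromoter(params)
    stopifnot(inherits(params, "fluorParams"))
    if (any(red <= 0)) stop("nonpositive red signal")
    if (any(green < 0)) stop("negative green signal")
    raw <- 1 / (1 + params$lambda * (green / red - params$beta))
    # lambda*(G/R - beta) <= -1 sends the raw estimate past +Inf; treat as
    # fully variant 1
    raw[!is.finite(raw) | raw < 0 & (green / red) < params$beta] <- 1
    out <- pmin(1, pmax(0, raw))
    if (any(out != raw))
        warning("raw fluorescence ratio outside [0, 1]; clamped")
    out
}

#' Batch fluorescence quantification from a TSV
#'
#' Reads a table with columns `sample`, `promoter`, `red`, `green`, applies
#' [omegaFromFluorescence()] row-wise with each row's bundled promoter
#' parameters, and returns (or writes) the table with an `omega` column.
#'
#' @param input path to the input TSV.
#' @param output optional path for the augmented TSV.
#' @return the augmented `data.frame`, invisibly when written.
#' @export
fluorBatch <- function(input, output = NULL) {
    tab <- read.delim(input)
    need <- c("sample", "promoter", "red", "green")
    if (!all(need %in% names(tab)))
        stop("input must have columns: ", paste(need, collapse = ", "))
    tab$omega <- vapply(seq_len(nrow(tab)), function(i)
        omegaFromFluorescence(tab$red[i], tab$green[i],
                              paramsForPromoter(tab$promoter[i])),
        numeric(1))
    if (is.null(output)) return(tab)
    write.table(tab, output, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(tab)
}
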