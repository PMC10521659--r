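Package: qsanger
Title: Quantification of Two-Variant DNA Mixtures from Sanger Electropherograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the relative abundance of two DNA variants in a mixed
    population directly from a mixed Sanger sequencing electropherogram. The
    mixed trace is aligned against two single-variant reference traces with a
    peak-aware global alignment, the references are warped into the mixed
    read's time and amplitude frame via anchor points where both variants
    carry the same base, and the mixture fraction is obtained by closed-form
    least squares at reference-divergent peak positions. Includes an ABIF
    (AB1) chromatogram reader, a fluorescence-reporter based estimator of the
    same fraction for cross-validation, and a synthetic chromatogram
    simulator with known ground truth so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'qsanger-package.R'
    'AllGenerics.R'
    'RcppExports.R'
    'config.R'
    'chromatogram-class.R'
    'peaks.R'
    'align.R'
    'fluor.R'
    'warp.R'
    'ratio.R'
    'simulate.R'
    'trace-io.R'
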