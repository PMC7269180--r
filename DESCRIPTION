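Package: peakdecon
Title: Cell-Type Deconvolution of Bulk Chromatin Accessibility Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Partial deconvolution of bulk ATAC-seq (and, more generally,
    gene-expression) mixtures. Builds a condition-number-optimized signature
    matrix of cell-type-specific peaks from labeled reference samples using a
    one-vs-each intersection-union test, automatically transforms the data via
    Box-Cox lambda estimation, and estimates cell-type proportions by solving
    m = B * f with SIMPLS partial least squares followed by nonnegativity
    clipping and sum-to-one normalization. Includes evaluation statistics
    (RMSE, Pearson correlation, a Monte-Carlo Wasserstein-distance p-value),
    an intensity-level mixture simulator for validation, and a command-line
    interface covering the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    MASS,
    limma,
    jsonlite,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
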