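Package: pbvoom
Title: Group-Aware voom Precision Weights for Pseudo-Bulk Single-Cell
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression analysis of pseudo-bulk single-cell
    RNA-seq data when experimental groups have unequal variability.
    Implements the voom mean-variance precision-weight framework together
    with two group-heteroscedasticity-aware extensions: group-specific
    mean-variance trends with per-group observation weights (voomByGroup),
    and block-constrained sample quality weights (voomQWB). Includes
    empirical-Bayes moderated t-tests, group-wise common biological
    coefficient of variation (BCV) estimation via Cox-Reid adjusted profile
    likelihood, a correlated gamma-Poisson (negative binomial copula)
    single-cell count simulator with known differential-expression truth,
    and an FDR/power benchmarking harness, plus mean-variance and MDS
    diagnostic plots and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    Matrix,
    jsonlite,
    tibble,
    dplyr,
    ggplot2,
    generics,
    stats,
    utils,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
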