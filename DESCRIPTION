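Package: ProtArray
Title: Pre-Processing and Differential Expression for Single-Channel
    Protein Microarrays
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reads spot-level extractions of single-channel protein
    microarrays (GenePix GPR/ATF and Mapix-style tab-delimited files),
    filters noisy spots against a 2-SD background threshold, applies four
    background-correction methods including a maximum-likelihood
    normal+exponential (normexp) convolution model, normalizes by scale,
    quantile or fast cyclic loess, estimates per-array quality weights by
    REML scoring of a heteroscedastic linear model, consolidates replicate
    spots to one value per protein, and performs weighted empirical-Bayes
    moderated-t differential expression with Benjamini-Hochberg adjustment.
    Includes a synthetic array generator emulating common single-channel
    designs and evaluation utilities (MA tables, control-replicate
    coefficients of variation, residual-variance trends, filtering-strategy
    comparisons) so every stage can be benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    graphics,
    grDevices,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, Preprocessing, QualityControl,
    DifferentialExpression, Normalization, Software
RoxygenNote: 7.3.3
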