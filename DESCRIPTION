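Package: crossnorm
Title: Cross-Platform Normalization of Gene Expression Data and Its Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Makes gene-expression matrices measured on different microarray
    platforms directly comparable. Implements nine cross-platform
    normalization methods (quantile normalization, median rank scores, gene
    quantiles, quantile discretization, normal discretization, distribution
    transformation, empirical Bayes batch adjustment, XPN block-model
    normalization, and distance weighted discrimination via a convex solver),
    together with an evaluation harness: mean-mean concordance, Welch-test
    differential expression with Storey-Tibshirani q-values, ROC-like curves,
    over/under-detection areas, a smoothed-bootstrap benchmark with positive
    and negative controls, and a location-shift model of platform effects
    (hybridization signal, gene-wise interaction ANOVA, optimal least-squares
    shift, parameter transfer).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    car,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
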