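Package: microtempo
Title: Temporal Turnover, Assembly Processes and Co-Occurrence Networks
    for Microbial Community Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing temporal dynamics of microbial
    communities from OTU count tables: rarefaction and table transforms,
    Bray-Curtis and Sorensen dissimilarity, alpha diversity, principal
    coordinates analysis, permutational multivariate ANOVA (PERMANOVA),
    ANOSIM, Mantel tests, distance-based linear models with forward
    selection, time-decay-of-similarity regression with permutation and
    bootstrap inference, null-model partitioning of community assembly
    into deterministic and stochastic components, and random-matrix-theory
    thresholded co-occurrence networks with topology metrics and
    degree-preserving random baselines. Includes a synthetic community
    generator with known turnover rate, environmental filtering strength,
    site effects and planted correlation blocks for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
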