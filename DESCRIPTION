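Package: stresspanel
Title: Stress-Marker qPCR Panels: Quantification, Marker Selection and
    Tolerance Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for custom RT-qPCR stress-marker
    arrays: quantification-cycle (Cq) calling from raw fluorescence
    traces, amplification-efficiency validation from dilution-series
    standard curves, efficiency-corrected multi-reference-gene
    normalization to log2 expression ratios, ANOVA/Tukey significance
    screening, majority-rule selection of direction-consistent marker
    genes across genotypes and locations, a per-genotype stress matrix
    built from qualifying marker responses, and tolerant/sensitive
    classification of genotypes by correlation with reference
    genotypes. Includes a seeded synthetic-experiment generator with
    planted effects so every stage can be checked against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
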