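Package: ohclust
Title: Overlap Hierarchical Clustering of Fold-Change Gene Sets with
    Growth and Phenotype Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for transcriptome comparisons of cell-line
    panels against a parental reference. Builds per-array gene sets from
    fold-change thresholding, clusters arrays by overlap (Jaccard) distance
    between gene sets with Ward's linkage, runs a moderated two-class
    permutation differential-expression test with false-discovery-rate
    adjustment, estimates doubling times from MTT growth curves by
    log-linear fitting of the exponential region, and quantifies dome
    formation and transepithelial resistance phenotypes. Includes a
    seeded synthetic-data generator that plants a co-regulated probe
    block under a dominant-suppression regulatory structure so that every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    yaml
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
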