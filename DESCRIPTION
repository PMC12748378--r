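Package: ampcontext
Title: Amplification Context Profiling for an Anchor Oncogene Across Cohort,
    Single-Cell and Spatial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise the molecular context of a high-level
    copy-number amplification (by default CCNE1) in tumor cohorts and in
    single-cell and spatial transcriptomic sections. Implements stratified
    amplification-rate estimation with between-stratum tests and
    co-alteration frequency profiling from GISTIC-style call tables;
    quartile-based marker-high/low stratification of epithelial cells with
    Wilcoxon rank-sum differential expression; a spatial colocalization
    screen based on nearest-neighbor Euclidean distances to anchor-high
    regions with expression-permutation nulls and Mann-Whitney tests; and
    database-agnostic hypergeometric overrepresentation analysis on
    user-supplied gene sets. Ships synthetic-data generators with planted
    ground truth for every stage, so the whole pipeline is testable
    end-to-end without external data.
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
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
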