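Package: socialmvpa
Title: Multivoxel Pattern Decoding and Representational Similarity Analysis of
    Self- Versus Other-Referential Brain Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style pipeline for region-of-interest and searchlight
    multivoxel pattern analysis (MVPA) of condition-by-run beta patterns, built
    around a factorial social-cognition design (four person identities crossed
    with emotive valence). Provides a synthetic-cohort generator with
    controllable representational geometry, seven leave-one-run-out
    cross-validation and cross-classification decoding schemes over a linear
    support vector machine, pairwise combinatorial-ROI joint decoding,
    whole-volume searchlight mapping with max-statistic permutation familywise
    error control, representational similarity analysis with rank-based model
    comparison and noise ceilings, and the shared group-level statistics
    (one-sample t tests against chance, exact signed-rank tests, Bonferroni
    adjustment, 2x2 repeated-measures ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
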