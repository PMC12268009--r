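Package: sexomics
Title: Multi-Omics Analysis of Sex Differences in Exercise Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sex differences in skeletal-muscle
    multi-omics (methylome beta values, transcriptome log2 intensities,
    label-free proteome abundances) from a two-sex endurance-training
    cohort sampled at baseline, after an acute exercise bout, and after
    training. Provides per-feature linear models with empirical-Bayes
    variance moderation and an age covariate, paired timepoint contrasts
    with fold changes, Benjamini-Hochberg adjustment, bump-hunting
    detection of differentially methylated regions with a permutation
    null, proteome preprocessing (total-amount normalization,
    group-completeness filtering, downshifted-normal imputation of
    missing-not-at-random values), direction-aware linking of CpG
    methylation to transcripts via promoter/gene-body rules and onward
    to proteins, fiber-type and mitochondrial proteome scoring with a
    training equalization analysis, hypergeometric over-representation
    analysis, and a seeded synthetic-cohort generator with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
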