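Package: diallelgp
Title: Genomic Prediction and Additive-Dominance GWAS for Partial-Diallel Maize Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether marker-trait associations discovered in
    inbred parental lines carry over to the prediction of their single-cross
    hybrids. Implements marker quality control and in-silico hybrid genotype
    construction from homozygous parents, mixed-model adjusted means and
    heritabilities for unreplicated augmented-block trials under two nitrogen
    regimes, the low-nitrogen tolerance index (LNTI), trace-normalised and
    VanRaden-type additive and dominance genomic relationship matrices with a
    Gaussian kernel, genomic prediction by marker-assisted selection (MAS),
    GBLUP, RKHS regression, BayesB and MAS-augmented kernel models with
    training-testing cross-validation, and additive-dominance single-marker
    mixed-model association scans with permutation-based family-wise
    significance thresholds and per-marker heritability decomposition. A
    seeded synthetic-data generator emulates two heterotic groups of fully
    homozygous parents, a partial diallel of single crosses and augmented
    block yield trials, so the whole pipeline can be exercised and validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
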