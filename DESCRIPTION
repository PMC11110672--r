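Package: flowerhabit
Title: Flowering-Habit Ontology Classification and Heritability for Biennial Vegetable Germplasm Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing flowering habit in heterogeneous biennial
    vegetable germplasm (carrot-style diversity panels) from two-timepoint
    percent-flowering scores in multi-year randomized complete block trials.
    Provides a synthetic germplasm-trial simulator with known category truth,
    5-point field-score quantization and senescence QC, Rosner's generalized
    extreme Studentized deviate outlier screen, estimated marginal means per
    accession, a two-timepoint flowering-habit ontology classifier (with a
    three-category baseline), Type III ANOVA, variance components and
    broad-sense heritability, and grouped Pearson trait correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    car,
    emmeans,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
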