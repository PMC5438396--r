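Package: etminer
Title: Data-Mining Pipeline for Cortical Roughness Morphometry in Essential Tremor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a case-control morphometry data-mining pipeline built
    around cortical "roughness" (the standard deviation of regional cortical
    thickness): parsing of FreeSurfer-style stats tables into a 281-feature
    structural schema, a seeded synthetic cohort generator with subgroup-level
    Gaussian feature tiers, univariate group statistics with parametric /
    non-parametric test selection and compact letter displays, a six-measure
    ensemble feature ranking (chi-squared, one-rule accuracy, information
    gain, gain ratio, Gini gain, symmetrical uncertainty), five classifiers
    behind one train/predict contract, a ranked-fragment sweep under
    stratified 10-fold cross-validation, and ordered decision-list rule
    induction with a pureness stopping criterion for descriptive subgrouping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
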