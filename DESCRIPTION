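Package: simma
Title: Salivary Biomarker Screening and Caries Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a salivary-biomarker caries risk test from
    longitudinal marker panels: univariate Wilcoxon rank-sum screening with a
    quantile-interval non-overlap criterion, per-category biomarker selection,
    a classification-power statistic (sensitivity + specificity) estimated by
    repeated stratified cross-validation of a single-hidden-layer neural
    network, a random-subset null distribution of that power, and a two-tier
    patient risk report combining per-marker reference-interval flags with a
    multivariate risk probability. Includes a synthetic-data generator that
    emulates the longitudinal structure of a 24 h post-toothbrushing sampling
    design with circadian and plaque-maturity effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    nnet,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
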