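Package: methtrace
Title: Multi-Cancer Detection and Signal-Origin Localization from
    Plasma cfDNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fragment-level analysis of targeted cell-free DNA (cfDNA)
    methylation sequencing for multi-cancer early detection and
    cancer-signal-origin (CSO) localization. Segments CpG sites into
    methylation-correlated blocks (MCBs), quantifies per-sample
    methylated fragment counts and ratios over those blocks, selects
    diagnostic markers by mutual information against healthy controls,
    combines per-marker deviations from a healthy baseline into a
    coverage-weighted Fisher methylation score thresholded at a fixed
    training specificity, and localizes the signal origin of detected
    cancers with a stacked multiclass ensemble. A synthetic-cohort
    generator with planted marker signatures and stage-scaled tumor
    fraction makes the whole pipeline testable without restricted
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
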