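Package: methsemi
Title: Semi-Supervised Cancer Subtype Classification from DNA Methylation
    Beta Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies tumour samples into molecular subtypes from Illumina
    methylation array beta-value matrices using a feed-forward neural network
    trained semi-supervisedly: supervised pre-training on labelled cohorts,
    then pseudo-label fine-tuning on unlabelled cohorts under a ramped
    unlabelled-loss weight. Includes a methylation-specific preprocessing
    pipeline (common-probe intersection across cohorts, high-missingness CpG
    filtering, median/mean/KNN imputation), multiclass evaluation metrics
    (accuracy, macro precision/recall, weighted F1, Matthews correlation
    coefficient, Cohen's kappa), a class-conditional synthetic methylome
    generator for benchmarking, and a command-line interface.
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
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
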