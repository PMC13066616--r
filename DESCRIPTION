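Package: sepshift
Title: Deployment Strategies for Sepsis Early-Warning Models Under Cross-Site Distribution Shift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking how sepsis early-warning models built on one
    intensive-care cohort behave when deployed at another. Provides a synthetic
    multi-site ICU cohort generator with controllable per-feature covariate
    shift, strict Sepsis-3 hourly labeling (suspicion of infection, onset
    confirmation, admission-window exclusions), the standard preprocessing
    stack (temporal splits, nested training subsets, missingness flags with
    forward-fill imputation, train-only standardization, 6-hour windowing),
    three compact sequence classifiers trained with a reproducible protocol,
    five deployment strategies (generalization, fine-tuning, retraining,
    fusion training, and supervised domain adaptation with multi-kernel MMD
    or CORAL alignment), covariate-shift quantification (two-sample
    Kolmogorov-Smirnov tests with Benjamini-Hochberg correction and absolute
    Cohen's d effect sizes), threshold-free evaluation including prevalence-
    normalized AUPRC, and paired Wilcoxon strategy ranking with Bonferroni
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    yaml,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
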