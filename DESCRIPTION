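Package: rpskit
Title: Response-Probability Scores for Predicting Neoadjuvant Chemotherapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational framework for building and applying
    response-probability scores (RPS) that predict pathologic complete
    response to neoadjuvant chemotherapy from pretreatment gene expression
    profiles. Per-gene logistic regression on a labelled training cohort
    yields paired up/down weight profiles; single samples are then scored
    with a rank-based foreground/background cumulative statistic normalized
    against a permutation null. Includes microarray preprocessing (probe
    collapse, quantile normalization, batch adjustment), comparator module
    scores, ROC/AUC and cross-validated random-forest evaluation,
    walking-sum pathway enrichment, and a synthetic-cohort generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    sva,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
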