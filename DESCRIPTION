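Package: csfpred
Title: Positive-Unlabeled Prediction of Cerebrospinal-Fluid Proteins and
    Biomarker Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a human protein is secreted into
    cerebrospinal fluid (CSF) from its amino-acid sequence.  Builds a
    1610-dimension descriptor vector per protein (composition, dipeptides,
    autocorrelation, quasi-sequence-order, pseudo-amino-acid composition
    and physicochemical profiles), removes irrelevant dimensions with a
    rank-sum/FDR screen and redundant ones with q-value-ranked recursive
    feature elimination, and fits a positive-unlabeled bagging ensemble of
    small feed-forward networks with out-of-bag probability averaging.
    Downstream helpers call differentially expressed genes by rank-sum
    test and fold change, map them to proteins and intersect them with
    predicted CSF proteins to nominate fluid biomarker candidates.
    Synthetic-data generators make the whole pipeline testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
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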