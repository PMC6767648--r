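Package: avadx
Title: Gene Functional-Deficit Scoring and Exome-Based Disease Status Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts per-individual exonic variants into gene-level
    functional-deficit scores, selects disease-informative genes by in-fold
    feature selection (case-exclusive patterns, Kolmogorov-Smirnov and t-test
    screens, and a cost-sensitive DKM merit ranking), trains support vector
    machine models under family-aware leave-one-out cross-validation with
    minor-class bootstrap balancing, removes inter-panel batch effects with a
    mean-only empirical-Bayes adjustment applied per test individual, and
    evaluates predictions with permutation nulls, ROC/PR curves, and
    precision/recall/MCC at calibrated score cutoffs. Includes a synthetic
    diploid case-control cohort generator (VCF + annotation + phenotype) with
    planted disease genes, family structure, and batch shifts so the whole
    pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    sva,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
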