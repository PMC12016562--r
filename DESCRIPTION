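Package: scm6a
Title: Single-Cell m6A Quantification from Regulator Expression and
    Winscore-Based m6A-seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learning quantification of N6-methyladenosine (m6A)
    RNA-methylation levels in single cells from the expression of m6A trans
    regulators and cis sequence features, together with an improved
    winscore-based quantification pipeline for bulk m6A-seq (MeRIP-seq)
    IP/input window counts. Includes sliding-window RPKM enrichment scoring
    with pseudo-count adjustment, peak merging and splitting, per-site
    regression models (random forest, linear regression, k-nearest
    neighbours, linear and polynomial support vector regression) selected by
    grid search with k-fold cross-validation, a tolerance-label ROC/AUROC
    and balanced-accuracy evaluation protocol with permutation nulls,
    matched-window correlation, metagene peak-distribution profiles, and a
    synthetic-data generator with planted regulator-to-site effects for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    caret,
    e1071,
    jsonlite,
    limma,
    Matrix,
    pROC,
    ranger,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
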