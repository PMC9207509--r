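Package: m6ascore
Title: Consensus Clustering and Prognostic Scoring of m6A-Regulator
    Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Condenses the expression of the 16 N6-methyladenosine (m6A)
    regulator genes into a per-patient prognostic score. Provides resampled
    k-means consensus clustering with PAC-based selection of the number of
    clusters, empirical-Bayes (ComBat-style) batch correction for merging
    cohorts, moderated-t differential expression between clusters,
    random-forest and univariate-Cox gene trimming, a PCA-based score
    (sum of the first two principal-component sample scores), maximally
    selected log-rank cutpoints, Kaplan-Meier / Cox / time-dependent ROC
    survival statistics, single-sample and two-group gene-set enrichment,
    and a synthetic multi-cohort generator with recorded ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    randomForest,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    fgsea,
    pROC,
    mclust,
    withr
Config/testthat/edition: 3
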