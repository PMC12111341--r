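Package: reopair
Title: Relative Expression Ordering Gene-Pair Analysis for Tumor Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-based diagnostic and prognostic analysis of tumor
    transcriptomes built on within-sample relative expression ordering (REO)
    of gene pairs. Mines stable and stable-reversal gene pairs from labeled
    bulk expression, binarizes pair profiles into platform-independent
    features, fits and ranks a configurable grid of machine-learning
    diagnostic models by mean AUC, post-processes single-cell copy-number
    profiles (per-cell and per-cluster CNV scores, k-means secondary
    clustering with elbow-based cluster-number selection), scores per-cell
    metabolic pathway activity with ssGSEA- and AUCell-style rank statistics,
    and performs Cox proportional-hazards risk stratification with
    Kaplan-Meier and concordance-index summaries. Includes seeded synthetic
    generators that plant every signal the pipeline detects, so the whole
    workflow is testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    survival,
    glmnet,
    ranger,
    e1071,
    rpart,
    xgboost,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
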