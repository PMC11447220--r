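Package: tp53phenocopy
Title: TP53-Loss Phenocopy Signatures from Multi-Cohort Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Labels biallelic TP53 loss-of-function from mutation and
    copy-number tables under dataset-specific threshold schemes, harmonizes
    gene expression across cohorts by per-sample dense-rank normalization and
    reference-batch empirical-Bayes correction, trains and locks a
    pathway-restricted gradient-boosted classifier that calls TP53-loss
    phenocopies from expression alone, and runs the downstream association
    analyses (per-drug sensitivity models, Fisher tests on pathologic complete
    response, Cochran-Armitage trend tests on residual cancer burden and
    longitudinal timepoints). Ships a synthetic multi-cohort generator with
    planted genotype/phenotype/response structure so the whole workflow is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    xgboost,
    pROC
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
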