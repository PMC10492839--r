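Package: modulewas
Title: Gene-Module Analysis of TWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects gene-trait association statistics from transcriptome-wide
    association studies (TWAS) and drug-induced transcriptional profiles into a
    gene-module latent space learned by pathway-level matrix factorization
    (PLIER-style nonnegative loadings). Provides a correlation-aware generalized
    least squares competitive test for latent-variable/trait associations,
    including the analytic gene-gene correlation matrix derived from eQTL
    prediction weights and a reference genotype panel; a transcriptional
    signature-reversal drug-repurposing score with rank aggregation and
    gold-standard evaluation; an evidence-accumulation consensus clustering
    pipeline for traits with decision-tree extraction of cluster-discriminative
    modules; and synthetic-data generators with planted ground truth so the
    whole pipeline can be exercised and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    kernlab,
    mclust,
    rlang,
    rpart,
    stats,
    tibble,
    utils,
    uwot,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
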