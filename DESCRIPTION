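Package: pausescape
Title: Predictive Modeling of RNA Polymerase II Promoter-Proximal Pausing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies promoter-proximal RNA polymerase II pausing from
    strand-specific nascent-transcription coverage (GRO-seq style wiggle
    tracks) as a log2 pausing index, assembles region-resolved binary
    binding feature matrices from ChIP-seq and eCLIP-seq peak files
    together with gene annotation and sequence-composition features,
    trains gradient-boosted tree regressors of the pausing index with
    cross-validated and holdout evaluation, and ranks DNA/RNA-binding
    factors by additive (SHAP) feature attributions, including minimal
    influential-factor-set selection and functional-set enrichment.
    Ships a seeded synthetic-data generator that emits a complete file
    bundle (genome, GTF, peak BEDs, wiggle coverage, expression, CAGE,
    CpG islands) with planted causal binding factors and ground truth
    for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    xgboost,
    glmnet,
    ranger,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
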