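Package: epirisk
Title: Disease-Specific Prioritization of Non-Coding Variants from Epigenomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes non-coding risk variants for a single disease by
    contrasting binned epigenomic signal (ChIP-seq, DNase-seq, FAIRE-seq read
    counts or called peaks) at reported risk variants against matched benign
    controls. Controls are sampled to match the risk variants' distance to the
    nearest transcription start site (or genomic neighborhood). Informative
    features are screened per disease with two-sided t-tests (read counts) or
    Fisher's exact tests (peak presence) at a p-value threshold tuned by
    cross-validation, and a balanced bagging ensemble of base classifiers
    (decision tree, radial SVM, or lasso) corrects the class imbalance by
    resampling the benign set; the risk score of a variant is the mean of the
    base-learner probabilities. Includes evaluation protocols (stratified
    cross-validation, repeated independent tests, leave-one-disease-out),
    binomial over-representation analysis of factors among informative
    features, and a self-contained synthetic-data generator with planted
    enrichment and depletion for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ranger,
    e1071,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
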