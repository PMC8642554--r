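Package: smilegan
Title: Semi-Supervised Clustering of Disease Subtypes via Generative
    Adversarial Learning on ROI Volumes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the Smile-GAN approach to neuroanatomical subtype
    discovery: a generative adversarial network learns one-to-many sparse
    mappings from a cognitively normal reference group to a patient group,
    modulated by a latent one-hot subtype code that an inverse clustering
    network must recover, so that subtype membership is identifiable from
    the data. Includes covariate residualization and reference-group
    normalization of regional volumes, model selection by clustering
    stability (adjusted Rand index over repeated holdout cross-validation),
    ensemble consensus with optimal label matching, a synthetic cohort
    generator with ground-truth atrophy subtypes and longitudinal
    progression pathways, and survival-based evaluation of pattern
    progression (Kaplan-Meier, Aalen-Johansen competing risks, Harrell's
    concordance, horizon discrimination).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    survival,
    S4Vectors,
    SummarizedExperiment
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
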