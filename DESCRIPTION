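Package: rgpipe
Title: Radiogenomic Classification of Glioma Molecular Subtypes from MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for predicting IDH and TERT-promoter mutation status of
    WHO grade II/III gliomas from multi-sequence magnetic resonance images.
    Implements the two intensity-normalization dialects used for radiomic and
    convolutional feature branches, derived T2-edge and contrast-enhancement
    z-score channels, first-order/shape/location radiomic features, lesion
    image cutting with crop/rotate/flip augmentation, a pluggable
    convolutional texture-feature extractor, patient-grouped nested
    cross-validation with univariate F-statistic screening and a linear
    support vector machine, balanced accuracy and precision-recall AUC from
    hyperplane distances, shuffled-label chance runs, and the accompanying
    statistics layer (one-tailed Welch tests against chance, one-way ANOVA
    with Tukey-Kramer post hoc and Bonferroni correction, chi-squared
    homogeneity tests, t-based confidence intervals). A synthetic-cohort
    generator with genotype-dependent lesion texture and age stands in for
    the non-public patient data so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
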