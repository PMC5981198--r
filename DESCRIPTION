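Package: radsig
Title: Radiation Exposure Gene Signatures by Biochemically-Inspired
    Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives and validates transcriptomic gene signatures of
    ionizing radiation exposure. Implements curated-panel preprocessing
    of gene expression matrices (completeness filtering, nearest-neighbor
    imputation, z-scoring, probe collapsing, cross-dataset
    harmonization), minimum-redundancy-maximum-relevance (mRMR) gene
    ranking under the mutual-information-difference criterion, radial
    basis function support vector machine classification of dose classes
    with a C/sigma grid search, complete/forward/backward sequential
    wrapper feature selection, signature-centric stratified k-fold and
    traditional (quantile-normalized train/test) external validation
    with misclassification, multi-class log loss and dose
    goodness-of-fit metrics, cross-signature frequency and gene-removal
    analyses, and a synthetic data generator with planted
    dose-responsive genes, redundant gene blocks, missing values and
    batch distortion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
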