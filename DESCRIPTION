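Package: spexfa
Title: Sparse Bayesian Factor Analysis of Spatial Gene-Expression Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes registered in situ hybridization images into a small
    set of latent spatial factors with sparse per-image mixing weights, using
    Gibbs sampling under a Student-t (Gamma-hierarchy) shrinkage prior.
    Includes grid-patch feature extraction from grayscale embryo images, a
    synthetic-corpus generator with planted annotation labels and enriched
    gene sets, loading-matrix analyses (clustering by dominant factor,
    cluster link graphs, non-informative image filtering), hypergeometric
    and chi-square gene-set enrichment, and automatic annotation of
    expression patterns via sparse multinomial logistic regression (L1-MAP)
    or a polynomial-kernel SVM, evaluated with gene-level leave-one-out
    cross-validation, majority/minority voting, AUC and recognition rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tools,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    png,
    tiff,
    e1071,
    generics
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
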