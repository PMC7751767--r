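Package: fieldomics
Title: Single-Plant Field Omics: Spatially Aware Correction, Networks and Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Field", "Omics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular profiles of individual field-grown
    plants. Provides a synthetic field-trial generator with spatially
    autocorrelated latent factors and planted gene modules; count and
    metabolite preprocessing (CPM filtering, median-of-ratios size factors,
    pseudocount log2 transform, Grubbs outlier masking, low-rank imputation,
    quantile normalization); per-feature linear models with spherical-variogram
    correlated errors fitted by restricted maximum likelihood, variance
    decomposition and residualization; Moran's I spatial autocorrelation
    screening and cluster-phenotype association; normalized-CV expression
    variability scoring; spatially adjusted co-expression network inference
    with guilt-by-association gene function prediction and benchmarking; and
    nested cross-validated phenotype prediction with permutation p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    igraph,
    limma,
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
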