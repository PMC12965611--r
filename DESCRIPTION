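Package: mographdrp
Title: Multi-Omics and Molecular-Graph Drug Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts log-scale drug sensitivity (ln IC50) for drug/cell-line
    pairs by fusing four omics profiles of the cell (gene expression, binary
    mutation status, DNA methylation and pathway activity scores) with a dual
    structural representation of the drug: a graph convolutional encoding of
    the heavy-atom molecular graph and compressed Morgan, substructure-key and
    SMILES-subword fingerprints.  Cell and drug embeddings interact through a
    multi-head bilinear attention module whose fusion vector feeds both an MLP
    prediction head and a gradient-boosted tree refiner that corrects residual
    error.  Includes loaders for delimited omics matrices and response tables,
    a decile-stratified splitter, regression metrics, missing-entry imputation
    with drug ranking, an ablation harness, and a seeded synthetic-data
    generator so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    ChemmineOB,
    ChemmineR,
    Matrix,
    data.table,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
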