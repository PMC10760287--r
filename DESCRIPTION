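Package: nnprs
Title: Neural-Network Polygenic Risk Scores with Missing-SNP Compensation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains small neural networks to reproduce interaction-bearing
    polygenic risk score (PRS) formulas from effect-allele-count genotypes,
    compensates for missing input SNPs via multilayer perceptrons,
    autoencoder imputation and linear predictors, probes performance limits
    through a fixed catalogue of model variants, and exports trained
    networks as portable plain-text weight matrices evaluable with matrix
    arithmetic alone. Includes a linkage-disequilibrium-aware genotype
    simulator so every experiment runs on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
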