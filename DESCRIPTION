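Package: gwablup
Title: GWAS-Assisted Best Linear Unbiased Prediction of Genetic Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for GWAS-assisted genomic prediction (GWABLUP) in
    livestock-style datasets. Implements mixed-model (EMMAX-type) single-SNP
    association scans producing likelihood ratios, moving-average smoothing of
    the likelihood ratios along the genome, posterior-probability SNP weights,
    weighted genomic relationship matrices, GBLUP and SNP-BLUP prediction with
    heterogeneous residual weights, a BayesGC Gibbs sampler (GBLUP polygenic
    term plus BayesC-type selected SNP effects), a canonical-transformation
    multitrait extension, forward-validation statistics (reliability,
    dispersion bias, paired bootstrap), and a haplotype-mosaic synthetic-data
    generator emulating dairy-cattle yield-deviation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
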