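Package: logicgxe
Title: Logic-Forest Screening for Gene-Environment Interactions in
    Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects main effects and higher-order Boolean interactions
    between SNPs and binary environmental exposures in case-control data.
    Provides genotype/phenotype readers (TSV, PLINK raw, VCF), marker
    quality control (Hardy-Weinberg equilibrium in controls, minor-allele
    frequency, missingness, gene-region windows), recessive/dominant/
    genotypic binary encodings, an ensemble of Boolean logic trees fitted
    by simulated annealing to bootstrap samples, out-of-bag error,
    permutation (VI1) and frequency (VI2) importance for the prime
    implicants the ensemble identifies, permutation p-values by refitting
    on outcome-permuted data, univariate logistic confirmation, a
    synthetic-study generator with planted Boolean risk terms, and a
    config-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    vcfR,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
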