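Package: liabilityscan
Title: Single-Step Genomic BLUP Association Scans for Binary Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide association analysis for binary disease traits using
    single-step genomic BLUP (ssGBLUP) with a threshold-liability sire model.
    Builds pedigree (A) and genomic (G) relationship matrices and the combined
    H inverse, fits the liability model by Gibbs sampling with the residual
    variance fixed at 1, back-solves genomic breeding values into per-marker
    effects, iteratively re-weights the genomic relationship matrix by realized
    marker variances, and ranks 10-adjacent-SNP windows by the share of genetic
    variance they absorb. Ships a pedigree/genotype/phenotype simulator that
    emulates a daughter-design dairy population so the whole pipeline is
    testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
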