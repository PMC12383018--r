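Package: stepblup
Title: Single-Step Genomic BLUP, REML, and Weighted Single-Step GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for genomic evaluation of quantitative
    traits in livestock populations. Builds pedigree (A) and genomic (G)
    relationship matrices, combines them into the single-step H matrix,
    estimates variance components for univariate and bivariate animal
    models by EM-REML, solves Henderson's mixed-model equations for
    (genomic) breeding values with prediction-error-variance based
    accuracies, back-solves SNP effects from genomic breeding values with
    iterative SNP weighting (weighted single-step GBLUP), summarises SNP
    variance in genomic windows (weighted single-step GWAS), compares
    pedigree and genomic evaluations, and annotates significant SNPs
    against a gene table.  A gene-dropping simulator generates pedigrees,
    genotypes, and correlated bivariate phenotypes with known true
    breeding values so that every stage of the pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    Matrix,
    stats,
    utils,
    tools,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
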