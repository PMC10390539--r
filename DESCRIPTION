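Package: panelbench
Title: Reference-Panel Benchmarking for Genotype Imputation Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating genotype imputation accuracy as a function
    of reference-panel choice. Includes a synthetic structured-population
    generator (power-law site frequency spectrum, Balding-Nichols divergence,
    recombinant-mosaic haplotypes, admixture), a minimal Li-Stephens
    haplotype-copying imputer with Minimac-style per-variant estimated R2,
    pre-imputation variant harmonization and sample/site quality control
    (missingness, genomic relatedness, Hardy-Weinberg exact test), accuracy
    metrics (per-sample genotype concordance rate, allele-frequency-binned
    pooled squared Pearson correlation, confidence-stratified yields),
    population-structure diagnostics (LD pruning, identity-by-state
    multidimensional scaling, K-population admixture fitted by EM), and a
    frequentist dosage score test with lead-signal extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
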