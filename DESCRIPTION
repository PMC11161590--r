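Package: mrstrat
Title: Cell-Type-Stratified Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stratifies GWAS causal variants by cell type through
    sum-of-single-effects fine-mapping and Bayesian colocalization with
    per-cell-type eQTL summary statistics, selects and quality-controls
    genetic instruments per cell type (LD clumping, proxy substitution,
    allele harmonization, radial outlier removal, F-statistics), and
    estimates cell-stratified causal effects with a suite of two-sample
    Mendelian randomization estimators (Wald ratio, IVW, MR-Egger,
    weighted median, weighted mode, robust adjusted profile score)
    governed by a pleiotropy-driven method-selection decision tree.
    Includes a fully seedable synthetic-data generator for LD-structured
    regional summary statistics and instrument tables with planted
    causal effects and pleiotropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    data.table,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
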