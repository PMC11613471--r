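Package: stimqtl
Title: Stimulation-Response cis-eQTL Mapping with Permutation Calibration
    and Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting exposure-responsive gene-regulatory variants
    from paired multi-condition expression and genotype data, modelled on
    stimulation designs in primary immune cells. Implements variant- and
    sample-level quality control (exact Hardy-Weinberg test, genotype PCA,
    Gaussian-mixture expression outlier detection), per-condition differential
    expression with empirical-Bayes variance moderation, over-representation
    and gene-set enrichment analysis, cis-eQTL mapping with a beta-approximated
    permutation pass, response-eQTL (e2QTL) slope z-tests, LD computation from
    dosages, enumeration-based Bayesian colocalization, and assembly of
    GWAS-overlap trait-association tables. A negative-binomial synthetic-data
    generator with planted genetic and differential-expression effects makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    edgeR,
    fgsea,
    vcfR,
    yaml
Config/testthat/edition: 3
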