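Package: dnburden
Title: Unified Gene-Based Burden Testing of De Novo SNVs and CNVs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A framework for gene-based enrichment analysis of de novo
    single-nucleotide and copy-number variants in neurodevelopmental-disorder
    trio cohorts. Estimates relative per-gene mutation rates of exon-deleting
    deletions (<1 Mb) by regression on genomic covariates trained on a
    population structural-variant catalog, converts them to absolute de novo
    rates via the Watterson estimator, aggregates trinucleotide-context SNV
    rates per gene with cohort calibration, performs Poisson burden tests
    with a two-step multiple-testing correction, provides gene-set
    overrepresentation statistics with resampling p-values, and prioritizes
    candidate genes with a feed-forward neural network combined with
    kernel-density likelihood ratios and naive-Bayes posteriors. A forward
    Wright-Fisher drift simulator demonstrates the proportionality between
    per-gene mutation rates and segregating variant-site counts that
    underlies the rate model. A synthetic-data generator emulates every
    input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
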