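Package: rvscan
Title: Region-Based Rare-Variant Association Testing for Family and
    Case-Control Whole-Genome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-based association analysis of rare variants
    (alternate allele frequency at most 1%) in whole-genome sequencing
    cohorts. Implements genotype and sample quality control (exact
    Hardy-Weinberg test, Mendel errors, singleton and half-call filters),
    partitioning of post-QC variants into non-overlapping windows of ten
    consecutive variants, family-based burden and variance-component
    (SKAT-style) region tests with an exact or Monte-Carlo p-value from a
    within-sibship conditional permutation null, case-control burden,
    SKAT and SKAT-O score tests with covariate adjustment, rare-variant
    principal components from the Jaccard similarity index, Fisher
    combined-probability meta-analysis, and a synthetic-cohort generator
    so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
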