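Package: mtstruct
Title: Population Structure Analysis of Ancient Mitochondrial DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-level analysis of mitochondrial DNA
    haplotypes aligned to the rCRS coordinate system: within-population
    diversity (haplotype and nucleotide diversity with sampling variances),
    AMOVA-based Phi statistics with permutation inference, pairwise
    population Fst with Slatkin linearization and Benjamini-Hochberg
    correction, hierarchical-structure optimization over candidate
    population groupings, haplogroup-frequency binning with Ward clustering
    (bootstrap clade support) and PCA, minimum spanning networks of
    haplotypes, shared and ancestral haplotype lineage tracing, and
    sex-stratified re-analysis. Includes a seeded synthetic-data generator
    with ground-truth records for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
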