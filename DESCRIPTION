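Package: scThalamus
Title: Marker-Anchored Classification and Composition Analysis of Developing
    Thalamus Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing developmental single-cell RNA-seq of the
    caudal diencephalon: barcode-rank knee QC, counts-per-thousand
    normalisation, anchor-correlated marker panels and semi-supervised
    assignment of rostro-caudal progenitor domains, annotation transfer
    across time points by joint graph clustering, genotype-by-population
    composition tests (two-sided Fisher odds ratios), a running-sum
    enrichment score for a fixed Shh-responsive gene panel, expression-bin
    matched cell-cycle scoring, a graph Rayleigh-quotient score for
    spatially localized genes, and a ground-truth negative-binomial
    simulator of graded progenitor domains, bifurcating lineages, and
    genotype-specific depletion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
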