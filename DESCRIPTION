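Package: gmlink
Title: Gene-Metabolite Integration via KEGG Annotation, Module Clustering,
    Pathway Metagenes and Sparse PLS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating transcriptomics and metabolomics
    experiments. Maps free-text metabolite names to KEGG compound
    identifiers by a normalization and fuzzy-matching cascade, collapses
    ambiguous lipids into metabolite classes, cross-references gene
    symbols to KEGG genes and pathways from a cached flat-file snapshot,
    clusters metabolites into correlation modules by modulated modularity
    clustering (sigmoid-transformed absolute correlations with weighted
    Newman modularity maximized over the transform sharpness), summarizes
    per-pathway transcription as PCA metagenes, relates metabolite modules
    to pathway metagenes by sparse partial least squares, and builds
    unbiased top-K gene-metabolite bipartite correlation networks with SIF,
    TSV and GraphML export. Includes seed-deterministic synthetic-data
    generators emulating the two-condition factor structure the pipeline
    assumes, and a command-line entry point chaining the steps into a
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
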