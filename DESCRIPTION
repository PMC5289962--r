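Package: leucopan
Title: Pan-Genome Lineage Typing and Marker-Gene Quantification of Dairy
    Leuconostoc
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing Leuconostoc populations in mixed
    mesophilic (DL-type) dairy starter cultures from genome and amplicon
    sequence data. Provides ortholog clustering of annotated gene sets via
    an all-against-all protein similarity graph and Markov clustering,
    pan- and core-genome accumulation curves with Heaps-law style fits,
    lineage differentiation of genomes from the presence/absence pan-matrix
    with automatic cluster-count selection (L-method knee detection),
    screening of core genes for amplicon markers with conserved primer
    flanks around a variable region, and a paired-end amplicon pipeline
    (merging, quality filtering, exact dereplication, abundance-based
    denoising, reference classification) that estimates species composition
    across replicates. A synthetic-data module generates genome populations
    with planted lineage structure and mock-community reads so the whole
    chain can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    ape,
    igraph,
    methods,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
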