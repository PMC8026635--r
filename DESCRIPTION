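Package: prophageScreen
Title: Marker-Based Detection and Classification of Putative Plasmid Prophages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens bacterial plasmid sequences for putative plasmid prophages.
    Implements greedy identity/coverage sequence clustering for genome
    deduplication and marker protein-family construction, center-star multiple
    alignment and Krogh-style profile hidden Markov models for marker-gene
    screening (terminase, major capsid protein, tape measure protein, XerC-like
    tyrosine recombinase, ParA/ParM/TubZ partitioning motors, tail sheath,
    serine recombinase), bidirectional-best-hit orthology with COGtriangles
    cluster merging, a genome-by-cluster pangenome matrix exported as a
    bipartite protein-sharing network, shared-protein-content grouping of
    genomes, and a deterministic rule engine that calls each genome as a
    putative active, degenerated, or virulent-phage-like element with a tail
    morphotype and machine-readable evidence. Ships a synthetic plasmid
    generator with planted marker families, duplicates, group structure and a
    truth table for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'prophageScreen-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'align.R'
    'msa.R'
    'profile.R'
    'screen.R'
    'orthology.R'
    'grouping.R'
    'classifier.R'
    'cluster.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
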