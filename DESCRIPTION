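Package: carpr
Title: Ab Initio Discovery of Low-Divergence Repeat Families in Genome Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers recently active repeat families in a genome assembly by
    all-vs-all seed-and-extend self-alignment, merges alignment images into
    element instances and single-linkage clusters them into families with a
    full audit trail, builds per-family consensus sequences from
    length-constrained member samples, cleans and classifies consensus
    sequences against protein and transposable-element reference libraries,
    annotates the genome with the combined library using best-hit overlap
    resolution, separates segmental duplications from novel transposable
    elements by copy-number versus length analysis, and flags potentially
    active LINE elements by ORF and reverse-transcriptase domain scanning.
    Includes a synthetic-genome simulator with a machine-readable truth table
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    igraph,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Alignment, Annotation, RepeatDiscovery
RoxygenNote: 7.3.3
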