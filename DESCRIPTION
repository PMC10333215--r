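Package: endosym
Title: Comparative Genomics of Reduced Endosymbiont Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing the tiny, AT-rich circular genomes of
    heritable nutritional endosymbionts of sap-feeding insects.
    Implements reference-guided annotation with length-fraction
    pseudogene classification, essential amino acid biosynthesis
    pathway completeness and partitioning between co-resident
    symbionts, circular gene-order synteny with inversion calling and
    parsimony mapping of rearrangement events onto a host phylogeny,
    sliding-window quality control of long reads, and contig profiling
    with taxonomic binning.  A synthetic genome and read simulator with
    machine-readable planted truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
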