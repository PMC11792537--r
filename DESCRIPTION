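Package: dgrscan
Title: Prophage Discovery and Diversity-Generating Retroelement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying prophages in bacterial genome assemblies
    from sliding-window evidence tracks (gene organization, nucleotide
    content, read coverage breadth and depth), quantifying prophage
    induction from coverage ratios and split-read junctions, detecting
    diversity-generating retroelements (DGRs) by genome self-alignment with
    adenine-biased mismatch classification, measuring DGR activity from
    cognate-genome alignments and read pileups, and linking phages to their
    bacterial hosts through genome coverage and CRISPR spacer matches.
    Includes a fully seeded synthetic-data generator so every stage of the
    pipeline can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomeInfoDb,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
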