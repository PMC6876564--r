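Package: ccstail
Title: Poly(A) Tail Length and Composition Analysis from Long-Read
    Circular Consensus Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring mRNA poly(A) tail length and base
    composition from PacBio circular consensus sequence (CCS) reads of
    full-length cDNA libraries that retain the poly(A) tail. Covers
    edit-distance barcode demultiplexing with adapter trimming and
    concatemer resolution, poly(A) tail extraction from terminal
    soft-clips of spliced genome alignments, quantification of
    non-adenosine (U, G, C) residues within tail bodies, calibration
    against synthetic poly(A) spike-ins of defined tail length, gene
    assignment via merged exon models, alternative-polyadenylation site
    clustering, and a seeded synthetic-read generator with full ground
    truth so every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
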