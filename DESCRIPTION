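Package: intervalid
Title: Genomic Identifier Conversion by Absolute Coordinate Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts biological identifiers of any granularity (array
    probes, ESTs, transcripts, genes) between namespaces by representing
    every identifier as one or more intervals on a reference genome and
    querying augmented red-black interval trees with parameterized overlap
    rules (type, maxgap, minoverlap, select).  Includes a mismatch-tolerant
    short-sequence mapper for sequence input, BED/GFF3/FASTA readers and a
    UCSC custom-track writer, a confusion-matrix framework for scoring a
    conversion against a truth mapping, and a seeded synthetic genome and
    annotation generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    S4Vectors,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
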