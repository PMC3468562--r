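Package: barcodegap
Title: COI DNA-Barcoding Distances, Trees and Barcoding-Gap Species Delimitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing aligned cytochrome c oxidase subunit 1 (COI)
    DNA-barcode fragments: Kimura two-parameter (K2P) total, transitional and
    transversional distances with pairwise deletion; neighbor-joining trees
    with column-resampling bootstrap supports and species-monophyly tests;
    per-codon-position nucleotide composition; pseudogene (numt) quality
    control via frame, internal-stop, indel and codon-position substitution
    screening under the invertebrate mitochondrial code; barcoding-gap species
    delimitation with K2P and transversion-distance thresholds; and a
    community sequence simulator with full truth tables for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
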