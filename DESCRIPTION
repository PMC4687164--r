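Package: genaudit
Title: Resequencing-Based Audit and Correction of Finished Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects single-base discrepancies between short-read resequencing
    data and a finished bacterial reference genome, characterises their
    homopolymer context, classifies the coding consequences of correcting them
    (frameshift repair, premature-stop removal, merging of split genes),
    cross-validates corrected alleles against a related genome, and emits a
    corrected sequence with lifted annotation and tabular reports. Includes a
    lightweight seed-and-extend read mapper with pileup construction, a
    consensus discrepancy caller with indel left-normalisation, per-CDS
    coverage-breadth statistics, and a synthetic-data generator that produces
    a genome, a homopolymer-corrupted assembly, paired-end reads and a truth
    table so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
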