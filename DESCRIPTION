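Package: hml2scan
Title: HML-2 (HERV-K) Insertional Polymorphism Detection and Target Site
    Duplication Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles a catalogue of HML-2 endogenous retrovirus loci (solo
    LTRs, proviruses and truncated proviruses) from RepeatMasker annotation
    tables, intersects the catalogue with deletion-type records from a
    structural-variant table in the DGV dialect to nominate
    preintegration-allele candidates, and infers target site duplication
    (TSD) length, identity and mismatch load from the LTR-flanking genomic
    sequences by an anchored global-alignment search.  A synthetic-genome
    simulator plants ERV insertions with direct-repeat TSDs of known length
    and mutation load, together with matching annotation and variant files
    and a ground-truth ledger, so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    data.table,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
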