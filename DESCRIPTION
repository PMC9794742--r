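Package: eprvscan
Title: Discovery, Classification and Dating of Recently Inserted
    Endogenous Pararetroviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines genome assemblies for recently inserted, intact
    reverse-transcriptase (RT) domains of plant pararetroviruses
    (Caulimoviridae).  Provides a six-frame translated homology search
    (a tBLASTn surrogate with an adapter for external tabular output),
    screening for intact non-redundant RT loci (minimum length, no stop
    codons or frameshifts, tandem-array collapsing), greedy identity
    clustering at configurable thresholds (CD-HIT semantics), distance
    based neighbor-joining classification of clusters into operational
    taxonomic units with bootstrap support, minimum insertion-age
    inference from host divergence times, and ORF/domain-motif
    annotation of element architecture including a diagnostic rule for
    Wendovirus-like organisation.  A synthetic-genome simulator with a
    planted-element truth ledger supports parameter-recovery validation
    of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    rtracklayer,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
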