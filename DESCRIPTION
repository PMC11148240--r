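Package: msneoforge
Title: Frameshift Neoantigen Discovery from Coding Microsatellites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects microsatellite tracts (1-5 bp motifs) in a genome,
    restricts them to protein-coding regions, and represents the full
    spectrum of frameshift indels at each locus by two canonical in-silico
    deletions (the 3n+1 and 3n+2 frame classes). Mutant transcripts are
    translated to junction-excluded downstream frameshift peptides, from
    which MHC class I and class II epitope windows are enumerated, scored
    through a pluggable binding-affinity predictor interface, filtered on
    IC50, and annotated with physicochemical properties, variant- and
    gene-level evidence, and differential-expression labels. Candidates are
    persisted in a portable single-file store supporting "search" and
    "best neoantigen" queries. A synthetic-fixture generator with planted
    ground truth makes the whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
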