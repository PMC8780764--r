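Package: tuarchitect
Title: Transcription Unit Architecture from dRNA-Seq and Term-Seq End Profiles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls bacterial transcription start sites (TSS) from differential
    RNA-Seq 5'-end profiles, transcript 3'-end positions (TEP) from Term-Seq
    profiles using a leave-one-out modified z-score with two-replicate
    reconciliation, classifies both relative to annotated genes, assembles
    transcription units (TU) and TU clusters, and annotates cis-regulatory
    sequence elements (promoter -10/-35 boxes and spacers, U-rich terminator
    tails, heptameric direct repeats bound by Streptomyces antibiotic
    regulatory proteins). A strand-specific synthetic-data generator emulates
    a GC-rich actinobacterial genome with planted transcript boundaries for
    validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
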