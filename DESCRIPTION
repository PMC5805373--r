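Package: cistromics
Title: Multi-Factor Cistrome Co-Binding Analysis on an Accessible-Chromatin Null
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical analysis of transcription-factor co-binding from
    ChIP-seq peak sets: pairwise overlap significance under a binomial null
    restricted to accessible chromatin, multi-factor regulatory-hotspot
    detection, motif enrichment against TSS-distance-matched random peak
    sets, background-normalized regulatory-domain enrichment of peaks near
    gene sets, expression-threshold gene-set construction, and
    boundary-aware modeling of structural rearrangements (inversion plus
    deletions) with enhancer-promoter contact prediction. Ships a
    synthetic-data generator (genomes, accessible chromatin, co-bound peaks,
    planted motifs, expression tables) so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
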