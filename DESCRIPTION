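Package: quadmark
Title: Histone-Mark Inheritance Simulation and G-Quadruplex Motif Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of histone-modification inheritance through
    DNA replication on a one-dimensional nucleosome lattice, including
    replication-fork stalling and postreplicative gap filling with new,
    unmarked histones; detection of G-quadruplex consensus motifs
    (G3-5 L1-7 G3-5 L1-7 G3-5 L1-7 G3-5) on both strands of nucleotide
    sequences with gene-set prevalence comparison by Fisher's exact test;
    and the small ChIP-qPCR, delta-delta-Ct and methylation-fraction
    arithmetic used alongside such analyses. Deterministic synthetic-data
    generators make every component testable without external data, and a
    command-line interface exposes the simulator, scanner and assay tools.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
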