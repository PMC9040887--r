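Package: glycomine
Title: Resistance-Guided Genome Mining of HTH_42 DNA Glycosylase Subfamilies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for resistance-guided mining of bacterial biosynthetic gene
    clusters (BGCs) using HTH_42-superfamily DNA glycosylases as marker
    resistance genes. Classifies candidate proteins into the YQL, AZL and AZL2
    subfamilies by their catalytic motifs (QPhiD, (Q/H)PhiQ and HPhi(S/T)(D/E)),
    filters homology-search hits by e-value, identity and coverage, computes
    signed shortest distances from homolog genes to the nearest BGC on the same
    scaffold with an inside-cluster rule (within 5 genes or 2 kb), tallies
    per-genome copy-number and YQL/AZL coincidence censuses, extracts gene
    neighborhoods and functional-category ratios, summarises clade conservation
    on phylogenetic trees and alignments, and fits single-exponential
    glycosylase kinetics and Hill-equation IC50 dose-response models. A
    synthetic-data module generates multi-scaffold genomes, proteomes and assay
    data with a known ground-truth manifest so every stage is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    ape,
    phangorn,
    minpack.lm,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
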