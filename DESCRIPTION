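Package: cernaflow
Title: Integrative lncRNA-miRNA-mRNA ceRNA Network Analysis for Two-Group Microarray Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for competing endogenous RNA (ceRNA)
    discovery from two-group microarray intensity profiles of mRNAs, lncRNAs
    and miRNAs. Implements background-subtracted median normalization,
    detection-flag and intensity filtering, Welch-t differential expression
    with Benjamini-Hochberg false discovery rate control, positional
    classification of lncRNAs against protein-coding loci, 300-kb cis-target
    windowing for intergenic lncRNAs, intersection of differential features
    with miRNA target tables, assembly of a tripartite lncRNA-miRNA-mRNA
    regulatory network, dense-module mining (MCODE-style), hub identification
    by degree, extraction of sponge-consistent ceRNA triads, and
    hypergeometric term over-representation. Ships a seeded synthetic-data
    generator with planted ground truth so every stage is testable end to end,
    plus fixtures of published miRNA-target interaction tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
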