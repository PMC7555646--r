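Package: lrrfam
Title: Genome-Wide Characterization of LRR Receptor-Like Kinase Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide characterization of the leucine-rich repeat
    receptor-like kinase (LRR-RLK) gene family in plant genomes. Identifies
    family members from Pfam-style domain hit tables (LRR plus kinase
    architecture rule with an E-value screen and a similarity-rescue merge),
    classifies members into the 24 canonical RLK-Pelle LRR subgroups by
    reference-anchored neighbor-joining phylogeny with bootstrap, summarizes
    exon/intron structure per subgroup, detects tandem duplication clusters
    (200 kb rule) and collinear segmental blocks by rank-space chaining,
    computes Nei-Gojobori (NG86) Ka/Ks with Jukes-Cantor correction and dates
    duplications via T = Ks/2*gamma, scans 2-kb promoters against an IUPAC
    cis-element library, and profiles tissue-specific and infection
    time-course expression (tau specificity, peak calling, 2^-ddCt). A
    seeded synthetic-genome generator with machine-readable truth tables
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
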