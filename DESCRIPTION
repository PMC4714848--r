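Package: cesafam
Title: Characterization of the Cellulose Synthase (CesA) Gene Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-level and expression-level characterization of
    cellulose synthase (CESA) gene families, as applied to hexaploid wheat.
    Implements degenerate protein motif compilation and scanning
    (PROSITE-style fixed-residue/wildcard grammar), detection of the
    N-terminal zinc-finger (RING-like) domain and its deletion variants, the
    D/DXD/D/QXXRW catalytic signature, Kyte-Doolittle transmembrane segment
    calling, and classification of CESA proteins into primary (PCW) versus
    secondary (SCW) cell wall classes from two diagnostic motifs (the CXXC
    dipeptide within the zinc finger and the SXXCEXWF motif of the second
    transmembrane domain). Also provides intron-phase computation from gene
    models, Poisson-corrected neighbor-joining phylogenetics with column
    bootstrap, counts-per-million expression normalization with Ward/Pearson
    clustering, and a seeded synthetic-data generator that emulates
    CESA-like proteins, gene models, evolved protein families and two-group
    RNA-seq count matrices with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    phangorn,
    jsonlite
Config/testthat/edition: 3
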