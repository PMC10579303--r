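Package: nitriquant
Title: Copy-Number-Corrected Marker-Gene Quantification of Nitrifier
    Communities
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies nitrifier guilds (ammonia-oxidizing archaea and
    bacteria, comammox and canonical Nitrospira) in soil metagenomes and
    metatranscriptomes from protein-coding marker genes.  Implements
    phylotype construction by greedy identity-threshold dereplication of
    marker proteins with family assignment against a labelled reference
    panel, best-hit classification of peptide reads, RPKM normalization
    with per-guild gene copy-number correction against the single-copy
    rpoB anchor, per-phylotype transcript-to-gene activity ratios,
    per-lineage rpoB-normalized log2 expression profiles with
    absent/not-detected states and fold comparison against pure-culture
    reference profiles, and core versus lineage-specific protein-cluster
    classification from pangenome presence/absence matrices.  A synthetic
    community simulator with closed-form ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
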