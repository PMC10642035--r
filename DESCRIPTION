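Package: oxbsdm
Title: Cell-Type Differential DNA Modification Analysis from Paired
    Bisulfite and Oxidative Bisulfite Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Resolves 5-methylcytosine (mC) and 5-hydroxymethylcytosine
    (hmC) from paired bisulfite (BS) / oxidative bisulfite (oxBS)
    sequencing call tables and from TET+/TET- enzymatic methyl
    sequencing, with spike-in based conversion-efficiency estimation and
    correction. Calls differentially methylated and hydroxymethylated
    regions over fixed genomic tiles with a binomial likelihood-ratio
    test and a step-up q-value, quantifies genic-feature enrichment by
    log odds with Woolf confidence intervals and Fisher's exact test,
    computes metagene modification profiles stratified by expression
    tertiles, and summarizes repeat-element modification levels. A
    synthetic-data module generates ground-truth genomes, modification
    landscapes, sequencing-arm call tables, spike-ins, and expression
    tables so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2),
    GenomicRanges,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    data.table,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: DNAMethylation, Epigenetics, DifferentialMethylation,
    Sequencing, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
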