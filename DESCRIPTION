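Package: mirISR
Title: Small RNA Analysis of Rhizobacteria-Induced Systemic Resistance miRNAs
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing workflow for discovering plant
    microRNAs that mediate induced systemic resistance (ISR) triggered by
    beneficial rhizobacteria such as Bacillus velezensis FZB42. The package
    cleans and collapses small RNA reads, identifies known microRNAs and calls
    novel hairpin-derived candidates, tests differential expression with a
    random-sampling two-proportion model and selects ISR candidates as the
    repressed intersection of two treatment contrasts, extracts pri-miRNA
    promoters by orientation and distance rules and scans them for
    defense-related cis-elements, validates targets with degradome (PARE)
    cleavage profiles classified into categories 0-4, and summarises results
    as GO enrichment and an exportable miRNA-target-GO network. A synthetic
    data generator with planted ground truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    data.table,
    yaml,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Sequencing, SmallRNA, DifferentialExpression, GeneRegulation,
    NetworkEnrichment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
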