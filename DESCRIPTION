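Package: lncMobility
Title: Cross-Species Mobile lncRNA Detection in Parasite-Host Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising long non-coding RNAs (lncRNAs)
    that move between a parasitic plant and its host through vascular connections.
    Provides a two-genome transcriptome and read simulator with recorded ground
    truth, dual-genome read assignment with a native/mobile/filtered rule,
    lncRNA identification (class codes, length/exon/expression filters, an
    ORF-based coding-potential test) and positional classification, FPKM
    quantification and transcript-level mobility calls with summary tables,
    abundance and correlation statistics, read-coverage and splice-junction
    evidence tracks, cis (genomic window) and trans (RNA-RNA hybridization)
    target prediction, hypergeometric term enrichment, transcription-factor
    family tallies, and Cytoscape-ready network export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, Annotation, Sequencing
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'methods.R'
    'seedIndex.R'
    'assignment.R'
    'quantify.R'
    'cisTargets.R'
    'classCode.R'
    'orf.R'
    'codingPotential.R'
    'transTargets.R'
    'cotransfer.R'
    'coverage.R'
    'enrichment.R'
    'simConfig.R'
    'genomeSim.R'
    'expressionSim.R'
    'lncrnaFilter.R'
    'featureSummary.R'
    'librarySim.R'
    'io.R'
    'lncMobility-package.R'
    'mobility.R'
    'mobilityStats.R'
    'tfFamilies.R'
    'network.R'
    'samIngest.R'
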