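Package: emastscan
Title: Discovery of Candidate EMAST Microsatellite Loci and Tumor
    Instability Calling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for discovering candidate EMAST loci (Elevated
    Microsatellite Alterations at Selected Tetranucleotide repeats) in
    animal genomes.  Scans genome sequences for maximal perfect tandem
    repeats of a tri- or tetranucleotide unit, learns 11-nt flanking
    motifs from a panel of known unstable human loci with a ZOOPS
    expectation-maximisation motif finder, filters and ranks repeat loci
    by dual-flank position-weight-matrix score and global-alignment
    percent similarity to the known panel, and calls per-marker
    instability and per-tumor EMAST status from paired normal/tumor
    repeat-unit counts.  Includes seeded synthetic-data generators
    (genomes with planted repeats and motifs, flank training sets, and
    repeat-count tables) so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    optparse,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, SequenceAnalysis, MicrosatelliteInstability,
    MotifDiscovery, SomaticMutation
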