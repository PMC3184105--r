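Package: PhageCompare
Title: Comparative Genomics and Physiology of ViI-Like Bacteriophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of ViI-like myovirus genomes and
    their growth physiology. Provides open-reading-frame prediction with a
    Shine-Dalgarno ribosome-binding-site screen, sigma-70 promoter consensus
    scanning, reciprocal-best-hit orthology with identity/coverage thresholds,
    three-way conserved/unique proteome partitioning, core-genome auditing,
    region-level protein identity, ortholog-anchor synteny blocks,
    Poisson-corrected protein distances with neighbor-joining trees and
    bootstrap supports, and estimators for one-step growth curves (eclipse,
    latent period, burst size), lysis inhibition and radiolabel incorporation.
    A synthetic-data module generates genomes, proteome triads, growth curves
    and label series with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotate.R'
    'compare.R'
    'genbank.R'
    'phylo.R'
    'physiology.R'
    'report.R'
    'seqio.R'
    'simulate.R'
    'utils.R'
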