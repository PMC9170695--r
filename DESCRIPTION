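Package: epidyn
Title: Chromatin-State and Accessibility Dynamics Along Staged Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative epigenome-dynamics toolkit for staged
    differentiation time courses (for example hPSC -> vascular mesoderm ->
    endothelial progenitor -> hematopoietic progenitor). It segments the
    genome into four chromatin states (H3K4me3-only, bivalent, H3K27me3-only,
    unmarked) with a multivariate Bernoulli hidden Markov model on binarized
    200-bp histone-mark bins, calls bivalent promoters and classifies their
    stage-to-stage transition modes, clusters temporal chromatin-accessibility
    profiles by fuzzy c-means and groups clusters into stage categories, scans
    peak sequences with position weight matrices and tests per-category motif
    enrichment by Fisher's exact test, intersects enriched factors with
    activated bivalent genes to nominate candidate regulators, aggregates
    ATAC cut-site footprints around motif occurrences, and classifies open
    regions by knockout-versus-wildtype accessibility fold change. A seeded
    synthetic-data generator with full ground-truth tables makes every stage
    of the pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    limma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
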