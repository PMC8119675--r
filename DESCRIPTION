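Package: domainscape
Title: Broad H3K9me2 Domain Calling, Hi-C Compartment Scoring, and
    Compartment-Aware Integration of Chromatin State Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing megabase-scale repressive chromatin
    domains and their relationship to three-dimensional genome
    organisation.  Calls broad H3K9me2-style enriched domains from
    binned ChIP-seq counts with a two-state Poisson hidden Markov model
    using genome-pooled parameters, classifies domain loss between
    conditions with a depth-normalised Poisson enrichment test, computes
    signed A/B compartment scores from intrachromosomal Hi-C contact
    matrices (matrix balancing, distance normalisation, first principal
    component of the correlation matrix), classifies the timing of
    chromatin-mark recovery after inhibitor withdrawal, selects genes by
    promoter-proximal methylation criteria, and integrates per-bin
    methylation change with compartment change.  Includes a synthetic
    data generator with planted ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
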