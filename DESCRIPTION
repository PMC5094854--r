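Package: gonadFISH
Title: Simulated smFISH Imaging and Automated Transcription-Site
    Quantitation for the C. elegans Distal Gonad
Version: 1.0.0
Authors@R:
    person("gonadFISH", "Developers", email = "gonadfish@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate multi-channel single-molecule FISH (smFISH)
    image stacks of the C. elegans distal gonad with full ground truth, and
    to analyze such stacks with an automated pipeline: gonad boundary and
    3-D nucleus reconstruction from DAPI, dual-method spot detection with a
    fixed threshold cascade, classification of nuclear active transcription
    sites (ATS, exon+intron colocalized) versus cytoplasmic mRNAs,
    intensity normalization to single-mRNA units, capped 3-D Voronoi cell
    assignment, spatial gradient profiles along the distal-proximal axis,
    niche (DTC) contact analysis, assumption-gated statistical test
    dispatch, and exponential half-life fitting from decay time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
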