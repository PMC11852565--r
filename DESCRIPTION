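Package: nbscreen
Title: Analysis Pipeline for Nanobody Discovery Campaigns Against Cas9
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of a nanobody (VHH) discovery campaign:
    repertoire census against a germline V/D/J reference (translation,
    deduplication, germline assignment, somatic-mutation and lysine
    counting, candidate selection, identity matrix and neighbor-joining
    cladogram), four-parameter logistic dose-response fitting with EC50
    extraction, a corrected-AUC sandwich-ELISA epitope-binning statistic
    with graph-based bin inference, mass-photometry calibration and
    Gaussian mixture deconvolution with stepwise complex assignment, and
    gel-based percent-cleavage time courses with an inhibition verdict.
    Ships synthetic-data generators with recorded ground truth so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
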