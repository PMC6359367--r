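Package: vhnet
Title: Levenshtein-Distance Network Analysis of Longitudinal Antibody
    Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines immunization time-course B-cell-receptor repertoire
    sequencing data for antigen-reactive antibody lineages. Unique heavy-chain
    variable-domain (VH) transcripts are clustered into homology components by
    thresholded Levenshtein-distance graphs, the threshold is selected with the
    HCDR3-ratio statistic, and components are ranked by growth in unique
    sequence count and average clonal frequency across time points. Includes
    amplicon preprocessing (primer trimming, quality filtering, greedy
    abundance-based error correction), CDR3 motif extraction, minimum-spanning-
    tree reductions for visualization, and a ground-truth repertoire simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    Biostrings,
    S4Vectors,
    jsonlite,
    mclust,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
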