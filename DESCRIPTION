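Package: sigmak
Title: Sigma-k Genome Distances and Whole-Genome Duplication Double
    Distances
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Representation and comparison of gene-order genomes with
    linear and circular chromosomes.  Implements the sigma-k family of
    rearrangement distances derived from the breakpoint graph (sigma-2 is
    the breakpoint distance, sigma-infinity the double-cut-and-join
    distance) and linear-time algorithms for the sigma-4 and sigma-6
    double distance between a singular genome and a duplicated genome,
    built on the ambiguous breakpoint graph.  Includes an exhaustive
    oracle over all square resolutions for validation, seeded instance
    generators emulating evolution after a whole-genome duplication, a
    command-line front-end, and Graphviz (DOT) export of the graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    optparse,
    Rcpp,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
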