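Package: cpdr
Title: Protein Complex Detection by Clique Percolation with Distance Restriction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects overlapping protein complexes in protein-protein
    interaction networks by merging maximal cliques under a shared-vertex
    condition and an induced-diameter restriction (CP-DR), alongside the
    classic clique percolation method (CPM) baseline. Includes an
    evaluation battery against gold-standard complex catalogs (overlap
    score, sensitivity, specificity, f-measure, overlapping rate,
    hypergeometric function enrichment), a planted-complex synthetic
    benchmark generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
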