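Package: ended
Title: Detection of Environmentally Driven Edges in Microbial Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and removes environmentally driven (indirect) edges from
    microbial association networks using four classifiers operating on
    environmental triplets - sign pattern, time-window overlap, interaction
    information with a permutation significance test, and the data processing
    inequality - together with their intersection combination. Ships an
    environment-coupled generalized Lotka-Volterra community simulator with
    known ground-truth interactions, a zero-delay local-similarity association
    network constructor with permutation p-values, and a benchmark layer
    (confusion counts, classification rates, and a multivariate hypergeometric
    random-removal model) so the edge classifiers can be validated end-to-end
    on synthetic time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
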