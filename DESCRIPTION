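Package: initclust
Title: Initial Cluster Analysis of Binary Sequences by Minimum Description Length
Version: 0.1.0
Authors@R: person("initclust", "developers", role = c("aut", "cre"),
    email = "initclust@example.org")
Description: Detects a significantly 1-dense initial segment in an ordered
    binary sequence using the minimum description length principle with
    normalized maximum likelihood. Implements the single-cut model under
    Jeffreys and flattened priors, a Fisher-information model-complexity
    term with an optional finite-size correction, and a logistic conversion
    of the description-length difference into a p-value. Includes
    Monte-Carlo experiments for null calibration and cut-point recovery,
    and a structural front end that orders protein residues by distance
    from a focal atom or point to build the binary sequence from a PDB
    file. A command-line interface ties the pieces together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
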