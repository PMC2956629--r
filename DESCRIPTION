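Package: multihit
Title: Exact Multiplicity-Constrained Hitting Sets for Drug Combination Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the selection of multi-drug combinations from cell-line
    response screens as a hitting-set problem with per-cell-line minimum (alpha)
    and maximum (beta) hit requirements and bounded set size d. Provides the
    screen preprocessing pipeline (duplicate resolution by highest assay
    concentration, row-wise z-scoring on a logarithmic scale, standard-deviation
    thresholding), a polynomial-time kernelization with an O(alpha*d*k^d) size
    guarantee, complete branch-and-bound solvers for the minimum-size and
    fixed-size maximum-hits objectives, a CPLEX LP format model exporter,
    brute-force reference oracles, and seeded synthetic instance and screen
    generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
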