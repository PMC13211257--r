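Package: hexktw
Title: Kill-the-Winner Immune Surveillance Dynamics on a Hexagonal Lattice
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic spatial simulator of microbial species competing for
    space on a toroidal hexagonal lattice under a two-threshold
    immune-surveillance rule: when community load and single-taxon dominance
    both exceed set fractions, a large fraction of the dominant taxon's cells
    is removed ("kill the winner"). Tracks community diversity through Hill
    numbers (orders 0, 1 and 2), includes a deterministic mean-field
    counterpart (shared logistic competition with mortality and the same
    threshold suppression), constructed-state fixtures for operator-level
    testing, TSV/JSON trajectory and snapshot I/O, and figure panels of the
    collapse, maintenance and intermittent-surveillance regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
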