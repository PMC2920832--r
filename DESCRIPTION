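Package: pseudowalk
Title: Correlated Random Walks Built from Ordered Pseudopod Extension
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic model of amoeboid cell movement in which cells
    advance by pseudopod splitting (alternating right/left at a fixed
    angle) interspersed with de novo pseudopodia extended in random
    directions.  Provides a seeded Monte Carlo trajectory simulator
    driven by five parameters (pseudopod size, splitting fraction,
    right/left alternation bias, splitting angle, and its angular
    spread), the matching correlated-random-walk theory (closed-form
    mean squared displacement, per-step and per-pair correlation
    factors, step size, turn angle, directional displacement), circular
    statistics (von Mises and wrapped Cauchy densities, sampling, and a
    symmetric bimodal von Mises fit), a cell-shape irregularity
    statistic computed from polygonal outlines via area-matched
    ellipses, and seeded synthetic-data generators for every input the
    package consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
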