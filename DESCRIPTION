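Package: fragmodes
Title: Matrix Population Models of Group Fragmentation Life Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Demography of simple multicellular life cycles that reproduce by
    group fragmentation. Enumerates all pure fragmentation modes (trigger
    size plus integer partition of offspring sizes) up to a maximal group
    size, supports probabilistic mixed modes and three fragmentation-cost
    regimes, builds the projection matrix of each life cycle on an arbitrary
    fitness landscape, computes long-term growth rates (leading eigenvalues)
    and stable group-size distributions, searches for optimal life cycles and
    maps optimality over landscape families, and cross-validates the
    deterministic rates with exact stochastic simulation and ODE integration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
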