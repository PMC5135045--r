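Package: larvaConn
Title: Biophysical Larval Dispersal Simulation and Microsatellite
    Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An individual-based Lagrangian larval-dispersal simulator
    (fourth-order Runge-Kutta advection through two-layer gridded ocean
    velocity fields, behaviour-dependent depth use, competence and
    settlement rules) coupled with a microsatellite population-genetics
    suite (Weir-Cockerham F_ST, Jost's D, rarefied allelic richness,
    isolation-by-distance Mantel tests, Monte-Carlo population assignment,
    error-tolerant parentage exclusion and self-recruitment). Includes
    synthetic generators for ocean velocity fields, coastal habitat grids
    and multilocus genotype datasets with known ground truth, so the whole
    pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    ncdf4,
    jsonlite,
    yaml,
    igraph,
    permute,
    geosphere,
    vegan,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
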