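Package: spatpanel
Title: Spatiotemporal Panel Analysis of Regional Attention Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for spatiotemporal analysis of regional panel data such as
    per-capita web search-volume indices observed across provinces and years.
    Provides rook-contiguity spatial weight matrices (edge lists, polygon
    derivation, GAL interchange), seasonal concentration statistics for
    monthly series, global and local Moran's I with analytic and permutation
    inference, maximum-likelihood estimation of spatial autoregressive,
    spatial error and spatial Durbin panel models with fixed or random
    effects, the Lagrange multiplier / Wald / likelihood-ratio / Hausman
    model-selection battery, direct-indirect-total effect decomposition, and
    seed-deterministic synthetic data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
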