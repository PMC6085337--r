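Package: mutualinet
Title: Trait Matching, Functional Diversity and Niche Structure in
    Mutualistic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how trait matching and functional diversity
    drive the assembly of bipartite plant-animal mutualistic networks.
    Implements degree-weighted RLQ ordination of plant traits, animal traits
    and a binary metaweb, fourth-corner permutation tests (row, column and
    combined sequential models), Moran's multi-test probability, range
    standardised Gower distances with principal-coordinates embedding and
    abundance-weighted functional dispersion, interaction-niche metrics
    (effective partner numbers and standardised Kullback-Leibler
    specialisation d'), and Bayesian hierarchical structural equation models
    with stochastic indicator variable selection fitted via JAGS. A
    synthetic-data module simulates trait-matching interaction networks and
    climate-driven functional diversity with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
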