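Package: effdyn
Title: Distribution Dynamics of Regional Healthcare-System Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures regional healthcare-system efficiency with input-oriented
    data envelopment analysis (BCC under variable returns to scale, CCR under
    constant returns to scale, and the scale-efficiency decomposition),
    discretizes efficiency into relative states by pooled percentile
    thresholds, and studies the distribution dynamics of those states with
    Markov transition matrices, stationary distributions, spatially
    conditioned (spatial Markov) transition matrices, and linear-probability
    transition equations with two-way fixed effects and cluster-robust
    standard errors. Includes a seeded synthetic panel generator with a known
    production frontier, known latent state dynamics, known spatial coupling,
    and known covariate effects, so every stage of the analysis can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pracma,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
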