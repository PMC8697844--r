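Package: socnetage
Title: Age-Related Change in Weighted Animal Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference pipeline for studying age-related change
    in social network integration from focal-follow grooming observations.
    Builds annual weighted grooming networks (mixed-sex and same-sex
    compositions) from dyadic grooming rates standardized by party
    co-membership time, computes seven node-level integration measures
    (directed degree and strength, weighted betweenness, Barrat local
    transitivity, eigenvector centrality), fits penalized-spline additive
    mixed models of each measure against age, dominance rank and reproductive
    status with individual identity as a random intercept, and evaluates
    significance of age effects and individual repeatability with
    node-randomized permutation tests. Includes a synthetic focal-follow data
    generator with known ground-truth effects for calibration and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    mgcv,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
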