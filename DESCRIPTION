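Package: crossfeedr
Title: Simulation and Analysis of a Two-Strain Cross-Feeding Yeast Mutualism
Version: 0.1.0
Authors@R: person("crossfeedr", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Deterministic consumer-resource models of an engineered
    Saccharomyces cerevisiae mutualism in which a lysine-overproducing,
    adenine-auxotrophic strain and an adenine-overproducing,
    lysine-auxotrophic strain cross-feed each other. Strain growth follows
    Monod (Michaelis-Menten) saturation in the partner-supplied metabolite
    with shared logistic crowding; free metabolite pools are modelled
    explicitly. The package integrates the resulting hybrid dynamical
    system under initial, intermittent, and continuous nutrient
    supplementation regimes, sweeps supplementation phase diagrams and
    dominance grids including an "ultimate overproducer" strain, analyses
    a minimal eco-evolutionary density-fraction reduction with an explicit
    death rate and its saddle-node bifurcation, fits Monod growth-rate
    curves from single-strain supplementation assays, and generates
    synthetic experimental datasets (growth-rate tables and plate-count
    coculture time courses) for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
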