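Package: vegopt
Title: Vegetation Optimality Modelling of Coupled Water and Carbon Dynamics
Version: 1.0.0
Authors@R:
    person("vegopt", "developers", email = "vegopt@example.org",
           role = c("aut", "cre"))
Description: A vegetation optimality model for water-limited and
    energy-limited ecosystems. Couples a multi-layer soil water balance
    (van Genuchten-Mualem hydraulics on a rectangular soil block) with a
    two-big-leaf canopy whose gas exchange follows Cowan-Farquhar optimal
    stomatal control at constant marginal water cost. Vegetation
    properties adapt at three time scales: stomatal conductance hourly,
    photosynthetic capacity, seasonal cover and fine-root distributions
    daily by marginal Net Carbon Profit hill climbing, and six long-term
    community parameters by shuffled complex evolution (SCE-UA) global
    optimization. Includes a stochastic daily weather generator with
    hourly disaggregation and an elevated-CO2 experiment protocol that
    separates medium-term from long-term vegetation responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
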