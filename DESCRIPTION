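Package: ventbiogeo
Title: Biogeographic Province Inference for Hydrothermal Vent Communities
Version: 0.1.0
Authors@R:
    person("ESR", "Analysis Team", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for delineating biogeographic provinces from site-by-species
    presence/absence data with geographically constrained multivariate
    regression trees. Community matrices are Hellinger-transformed and
    partitioned on latitude and (alternatively encoded) longitude; tree size is
    selected by repeated v-fold cross-validation and the 1-SE rule, and the
    sensitivity of the resulting provinces to the longitude encoding can be
    scanned. Also provides Raup-Crick probabilistic similarity with
    agglomerative clustering, Tamura-Nei (TN93) pairwise genetic distances with
    simple indel coding of alignment gaps, rate-based molecular divergence
    dating, and a province-structured metacommunity simulator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    Matrix,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
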