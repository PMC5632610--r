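Package: oscillate
Title: Comparative Phylogenetic Tests of Host-Range Oscillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-phylogenetic toolkit for testing whether oscillations
    in herbivore host range drive diversification. Implements permutation-
    calibrated phylogenetic signal for binary host-use traits under the
    two-state equal-rates Markov (Mk) model, Fitch and squared-change parsimony
    tracing, sister-clade contrasts in host diversity versus species richness
    (sign test and paired t test on log relative richness), phylogenetic
    generalized least squares with Pagel's lambda, and through-origin
    species-richness contrast regression (MacroCAIC). A synthetic-data module
    generates Yule trees, Mk traits, and host-record universes with tunable
    phylogenetic signal so that every stage of the pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    nlme,
    phangorn,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
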