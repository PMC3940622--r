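Package: hedgewalk
Title: Simulating Pollinator Movement in Hedgerow-Structured Agricultural
    Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A spatially-explicit individual-based modelling framework for
    central-place-foraging pollinators in agricultural landscapes.
    Landscapes are generated as grid-based Voronoi tessellations of crop
    fields separated by single-thickness wild field edges (hedgerows), and
    pollinators move as habitat-biased correlated random walks starting
    from a nest placed in the wild corridor network.  The package provides
    the landscape manipulations common to agri-environment policy
    experiments (converting whole fields to wild set-aside, removing
    individual hedges between adjacent fields), experiment protocols that
    sweep movement and landscape parameters over many replicate
    environments, per-trajectory movement statistics (maximum displacement
    from the nest, habitat switches, time in wild habitat), and
    mixed-model likelihood-ratio trend tests with Tukey-style post-hoc
    comparisons for analysing the resulting tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    lme4,
    multcomp,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
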