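Package: assemblage
Title: Individual-Based Community Assembly Simulation and Detection of
    Selection from Abundance, Genetic and Trait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, zero-sum (Moran) simulation of local community
    assembly under five death models: neutral, environmental filtering,
    mean-field competition, pairwise trait-mediated competition and
    beta-competition with distinct intra- and inter-specific weights.
    Recorded abundance trajectories constrain per-species coalescent
    simulations of nucleotide diversity, and each simulation is reduced to a
    fixed summary-statistic vector over three biodiversity axes (species
    abundances, genetic diversity, trait variation): distribution moments,
    Hill numbers, Spearman cross-axis correlations and local-to-regional
    trait divergence.  A random-forest workbench trains on labelled
    simulations, reports cross-validated confusion matrices and predicts
    assembly-model class probabilities for user-supplied datasets, so that
    the footprint of selection can be distinguished from neutrality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    ape,
    ranger,
    e1071,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
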