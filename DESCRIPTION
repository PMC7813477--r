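Package: cdhfold
Title: Folding Thermodynamics, Mechanics and Interaction Networks of
    Cadherin-23 EC1
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to dissect how a single point mutation reshapes the
    folding landscape and mechanical response of the outermost
    extracellular domain (EC1) of the hearing-loss protein cadherin-23.
    Implements a block Wako-Saito-Munoz-Eaton (bWSME) Ising folding model
    with single- and double-sequence state spaces, Debye-Hueckel
    electrostatics and secondary-structure-dependent conformational
    entropies, fit to scanning-calorimetry thermograms; a self-organized
    polymer (SOP) coarse-grained model with overdamped Langevin dynamics
    and constant-velocity force pulling, with rupture detection,
    worm-like-chain contour-length analysis and unfolding-pathway
    classification; normalization and midpoint extraction for thermal and
    chemical melts; bi-exponential stopped-flow kinetics with chevron
    analysis; circular cross-correlation maps of backbone dihedrals and
    persistence-filtered hydrogen-bond networks; and seeded synthetic-data
    generators so every stage runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
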