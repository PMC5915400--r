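Package: switchsim
Title: Spatial Simulation and Fitness Estimation for the Evolution of
    Mating-Type Switching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual-based lattice simulation of competition between
    mating-type switching and non-switching fission yeast strategies across
    cycles of asexual growth and mating, with Mendelian reseeding, fixation
    detection and density-by-cost invasion sweeps. Also provides
    selection-coefficient estimation from competition count data (log-ratio
    estimator, marker correction, sexual-fitness transform, generation
    accounting), binomial mutation-rate bounds from negative screens, an
    independent-asci sampling estimator, and a synthetic competition-data
    generator with known ground truth for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
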