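Package: trackchem
Title: Stochastic Track-Segment Chemistry of Water Radiolysis Under Ion
    Irradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Particle-based simulation of the physicochemical and chemical
    stages of water radiolysis along heavy-ion track segments.  Provides a
    species registry and reaction network extended with secondary products
    (O.-, O2, O2.-, HO2., HO2-), dissociation branching for ionized and
    excited water, a synthetic track-segment generator with a 10-10.1 keV
    deposition window, Brownian-dynamics and independent-reaction-times
    chemistry engines covering 1 ps to 1 us, a deterministic well-mixed
    kinetics oracle, and estimators for time-dependent G-values and
    track-segment yields G'(E) around Bragg-peak energies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
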