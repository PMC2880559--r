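Package: muscleloop
Title: Workloop Energetics of Muscle-Actuated Mass-Spring-Damper Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the mechanical energetics of skeletal muscles
    coupled to second-order (mass-spring-damper) loads. Implements a bilinear
    muscle contractile model with second-order excitation-contraction dynamics,
    forward simulation of the interconnected muscle-load system, power-optimal
    cyclic control via the Pontryagin minimum principle (bang-bang control,
    smoothed-switching homotopy, cyclic two-point boundary value problem),
    workloop energetics (cyclic work, damper dissipation, synergy ratios),
    impedance-matching calculations, bilinear system identification, and an
    emulated virtual-load experiment pipeline with stimulation waveforms,
    measurement noise, fatigue drift and randomised protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
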