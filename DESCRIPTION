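Package: biosensim
Title: Reaction-Diffusion Models of Microelectrode Biosensor Calibration
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Steady-state and time-dependent reaction-diffusion models of
    cylindrical single-enzyme amperometric microelectrode biosensors in
    free-flow calibration, agar, brain tissue, and tissue with an
    insertion-damage gap.  Provides analytic multi-region radial solutions
    built from modified Bessel functions, an explicit Runge-Kutta
    finite-volume transient solver, the calibration-correction factors that
    quantify how free-flow calibration underestimates tissue concentrations,
    one-parameter sensitivity sweeps, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
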