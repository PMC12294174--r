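Package: jujuspec
Title: Hyperspectral Variety Classification with Metaheuristic-Tuned
    Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete chemometrics workflow for classifying fruit
    varieties from visible/near-infrared hyperspectral images (400-1000 nm):
    white/dark reference reflectance calibration, region-of-interest mean
    spectrum extraction, Isolation-Forest outlier screening, spectral
    preprocessing (baseline correction, multiplicative scatter correction,
    Savitzky-Golay first derivative), competitive adaptive reweighted
    sampling (CARS) wavelength selection on a partial least squares core,
    Kennard-Stone sample partitioning, and radial-basis-function support
    vector machines whose cost and kernel-width hyperparameters are tuned
    by four population metaheuristics (zebra, genetic, particle swarm, and
    grey wolf optimizers). Ships a synthetic spectra generator emulating
    dried-jujube reflectance so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    kernlab,
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
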