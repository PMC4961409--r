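Package: popcollapse
Title: Stochastic Collapse Dynamics of Intestinal Bacterial Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference for bacterial population dynamics in the
    larval zebrafish intestine: logistic growth punctuated by Poisson-timed
    collapse events. Provides an exact event-driven simulator of the stochastic
    collapse model, detection of collapse events in imaging-derived abundance
    time series, Poisson estimation of collapse rates and magnitudes,
    log-linear growth-rate estimation, simulation-based grid-search fitting of
    the carrying capacity K and collapse intensity z to censored endpoint
    abundance ensembles (plating-style data with limits of detection and
    quantification), out-of-sample endpoint prediction, spatial statistics for
    bacterial biogeography (axis densities, distance-to-wall distributions, a
    uniform space-filling null model, bootstrap confidence intervals), and
    synthetic-data generators with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
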