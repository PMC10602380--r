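Package: orderstates
Title: Establishing the Order of Brain-State Dynamics in Neuroimaging Timeseries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking what constitutes the state of a neural system:
    simulate first- and second-order linear stochastic dynamics, score both
    model orders on any multivariate timeseries with a variational
    free-energy (log-evidence) approximation built on an exact discrete-time
    Kalman likelihood, convert free energies into posterior model
    probabilities, and run cohort-level analyses (functional-gradient
    embedding, circular-shift surrogate nulls, temporal autocorrelation)
    on synthetic cohorts that emulate parcellated fMRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Matrix,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
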