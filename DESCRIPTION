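Package: boltzwalker
Title: Boltzmann Walker Analysis of 2-D Animal Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing noisy two-dimensional animal trajectories
    under the Boltzmann Walker (velocity-jump) framework: bottom-up
    piecewise-linear segmentation of tracked point series into straight free
    paths separated by reorientation events, estimation of direction-dependent
    motion parameters (speed, mean free path, phase-function persistence),
    axial circular statistics with the Hodges-Ajne uniformity test, and
    Monte-Carlo simulation of standard and heading-conditioned (extended)
    Boltzmann Walkers for dispersal prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
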