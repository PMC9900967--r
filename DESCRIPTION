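Package: slowmodes
Title: Metastable Langevin Dynamics on Slowly Fluctuating Potential Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and inference tools for heavy-tailed statistics of
    metastable behavioral dynamics. Provides an Euler-Maruyama engine for
    coupled fast/slow Langevin systems on a double-well landscape whose
    barrier height is modulated by a slow Ornstein-Uhlenbeck mode, frozen
    slow-mode ensembles and Kramers-rate Poisson surrogates, first-passage
    (residence) time extraction and power-law tail fitting, connected and
    non-connected autocorrelation estimators with finite-size corrections,
    kernel-based Kramers-Moyal drift and diffusion inference (stationary and
    time-dependent), and a transfer-operator pipeline that extracts a slow
    reaction coordinate from multichannel series by delay embedding,
    microstate clustering and spectral decomposition. A synthetic-data
    module generates behavior-like datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
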