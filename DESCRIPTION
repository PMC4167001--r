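Package: aeifrate
Title: Firing-Rate Approximations for Adaptive Exponential
    Integrate-and-Fire Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Steady-state firing rates of the exponential
    integrate-and-fire neuron with spike-triggered adaptation (aEIF)
    driven by Gaussian white or Ornstein-Uhlenbeck synaptic current
    noise.  Provides three analytical approximations built on the
    Fokker-Planck description of the model: the adapted EIF rate with
    mean adaptation current, a second-order correction from a
    perturbation expansion in the ratio of membrane to adaptation time
    constants, and an average of the EIF rate over a truncated-Gamma
    model of the adaptation-current distribution.  A fast
    Euler-Maruyama simulator, colored-noise corrections, and a
    validation harness comparing theory against simulation are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
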