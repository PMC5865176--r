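Package: dendriteLIF
Title: Event-Driven Leaky Integrate-and-Fire Perceptron with Synaptic and
    Dendritic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a feedforward leaky integrate-and-fire perceptron under
    periodic above-threshold stimulation, with spike-timing-dependent
    plasticity applied either to individual synaptic weights (per-link
    learning) or to shared dendritic weights (per-node learning). Provides an
    exact event-driven integrator with an Rcpp core, pairing of evoked spikes
    with sub-threshold stimulations under an exponential learning window,
    classification of weight trajectories as converged or oscillatory, and
    Monte-Carlo ensembles over random initial conditions that estimate the
    fraction of architectures whose dendritic weights self-oscillate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
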