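Package: lifmix
Title: Stimulus Mixtures in Leaky Integrate-and-Fire Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and likelihood-based inference for leaky
    integrate-and-fire neurons whose receptive field contains several
    stimuli. Implements two competing response hypotheses --
    probability-mixing (the neuron follows a single stimulus per trial,
    drawn with mixture probabilities) and response-averaging (the neuron
    integrates a weighted average of all stimulus currents) -- together
    with four numerical first-passage-time solvers (Fokker-Planck PDF and
    CDF equations solved by Crank-Nicolson, and first- and second-kind
    Volterra integral equations), marginal maximum-likelihood and EM
    estimation of the model parameters, and model selection through
    uniform spike-time residuals, Kolmogorov-Smirnov tests and DIC
    differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
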