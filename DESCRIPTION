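Package: sigstdp
Title: Sigmoidal Stochastic Simplified STDP with Binary Memristive Synapses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation toolkit for unsupervised learning with simplified
    spike timing-dependent plasticity (S-STDP) on stochastic binary synapses.
    Models a synapse as a pair of switching devices made of k serially
    connected binary memristors, whose cumulative switching probability
    follows a negative-binomial (discretised gamma) law and therefore gives
    the expected weight a sigmoidal dependence on the number of potentiation
    or depression trials. Includes the stateless switching statistics, a
    stateful device model with log-normal device-to-device variability, the
    deterministic and stochastic S-STDP update rules, a two-layer
    winner-take-all spiking network with Poisson rate coding of images,
    evaluation protocols for digit assignment, recognition accuracy and
    memory maintenance, synthetic pattern fixtures, and an experiment driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
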