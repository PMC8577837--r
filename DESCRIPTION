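Package: condmix
Title: Conditional Mixture Models for Correlated Neural Spike Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stimulus-conditional finite mixture models for multivariate
    neural spike counts, built on exponential-family parameterizations of
    independent-Poisson (IP) and Conway-Maxwell-Poisson-based (CB) mixtures.
    Provides maximum-likelihood fitting by expectation-maximization with
    Adam-ascended maximization steps, Bayesian decoding of discrete stimuli,
    closed-form Fisher information of minimal conditional mixtures, linear
    and multilayer-perceptron reference decoders, cross-validated model
    comparison via information gain, and seeded generators for randomized
    ground-truth models and information-limited synthetic populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
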