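Package: boutsim
Type: Package
Title: Reinforcement-Learning Simulation and Analysis of Bout-and-Pause
    Operant Response Patterns
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Time-stepped simulation of operant behavior organized into
    bouts and pauses. Q-learning agents choose between an operant and
    competing other behaviors (three-state dual-mechanism model, choice
    and cost knockout variants, and a two-state variant) on variable
    interval, tandem variable-time variable-ratio, fixed-ratio, and
    extinction schedules, with Fleshler-Hoffman interval tables. The
    analysis suite extracts interresponse times from event logs, draws
    log-survivor curves, fits static bi-exponential mixtures by
    constrained maximum likelihood and dynamic (exponentially decaying)
    bi-exponential models by Markov chain Monte Carlo with WAIC model
    comparison, estimates empirical state-transition probabilities, and
    fits the modern Herrnstein hyperbola (generalized matching law) to
    response-rate data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
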