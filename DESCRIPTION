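Package: dynobs
Title: Dynamic Bayesian Observer and Choice-History Models for Context-Switching Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for two-alternative forced-choice
    orientation discrimination in environments that switch between discrete
    stimulus contexts. Provides a generator for context-switching trial
    sequences (Markov context chain with a per-trial hazard rate, skewed
    orientation distributions, probabilistic context cues, contrast-dependent
    sensory noise), a hierarchical Bayesian ideal observer that filters a
    belief over contexts from noisy cues and four knowledge-ablated variants
    of it, psychometric bias estimation (point of subjective equality,
    aligned bias, bias as a function of trials since a context switch), a
    Signal Detection Theory process model of choice with lapses and bootstrap
    confidence intervals, and a dynamic Bernoulli GLM with a nonlinear
    trials-since-switch bias regressor, including parameter-recovery and
    model-comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
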