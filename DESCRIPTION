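Package: causalcap
Title: Bounded-Effect Causal Capacity Models with Generators, Reducers, and Blockers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing, evaluating, simulating, and estimating
    causal capacity models in which an effect with a bounded value range is
    driven by quasi-independent causes of three kinds: generators that push
    the effect up toward its upper bound, reducers that push it down toward
    its lower bound, and blockers that probabilistically switch off all other
    causal influence. The expected-effect equation generalizes the classic
    noisy-OR/AND model to continuous cause and effect magnitudes and contains
    the noisy-OR/AND, noisy-addition, and linear models as special cases.
    Includes a numerical axiom-checking engine for candidate two-argument
    combination functions, a brute-force polynomial solver that verifies the
    uniqueness of the privileged combination function, reduction verifiers
    for the special-case equivalences and limits, a synthetic trial-data
    generator with binary, narrow-continuous, and wide-continuous value-range
    regimes, bound-constrained maximum-likelihood strength estimation, and
    the classic delta-P and causal-power judgment estimators for 2x2
    contingency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
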