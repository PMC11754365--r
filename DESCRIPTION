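Package: goricct
Title: Theory-Based Hypothesis Evaluation for Contingency Tables with GORICA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates theory-based (in)equality-constrained hypotheses on
    multi-way contingency tables with the generalized order-restricted
    information criterion approximation (GORICA). Cell probabilities are
    reparameterized into marginal, conditional, or odds-ratio parameters so
    that hypotheses become linear constraint systems; point estimates and
    their covariance matrix are obtained by nonparametric bootstrapping, the
    order-restricted maximum log-likelihood is computed by projection under
    the multivariate-normal approximation, and the penalty (expected number
    of free parameters) is computed from Monte-Carlo level probabilities.
    Includes robust handling of sampling zeros via covariance repair, a
    bounded-simplex penalty mode for constraints stated directly on cell
    probabilities, and a selection-rate simulation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
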