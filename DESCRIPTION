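Package: nafc
Title: Sequential Bayesian Decision Making with Nonlinear Boundaries for
    Multiple Alternatives
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates n-alternative forced-choice (nAFC) perceptual
    decisions as sequential Bayesian evidence accumulation on the belief
    simplex, with decision rules given by a family of permutation-symmetric
    nonlinear boundary parameterizations (flat, curve, power, oscillatory).
    Provides a Monte-Carlo trial engine with linear speed/accuracy reward,
    grid-search reward-landscape optimization with a delta-acceptance
    (degenerate set) rule, and derived behavioral analytics: speed-accuracy
    trade-off curves, implicit threshold dynamics extracted from boundary
    crossing beliefs, Hick's law fits, and closed-form belief-normalization
    identities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
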