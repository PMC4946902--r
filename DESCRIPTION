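Package: uncertainreach
Title: Uncertainty-Dependent Population Analysis of Reach Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for center-out and cue-uncertainty reaching
    sessions: Bayesian cue-weighting fits to reach behavior using von Mises
    prior/likelihood means, circular summary statistics (resultant length,
    circular variance, angular dispersion), Poisson generalized-linear-model
    cosine tuning with bootstrap preferred-direction significance,
    preferred-direction-offset population maps and same/orthogonal/opposite
    direction rate comparisons regressed on behavioral uncertainty, and a
    preferred-direction-binned cosine decoder of single-trial reach direction.
    Includes a synthetic session generator that emulates the task (von Mises
    target prior, noisy cue lines, Bayesian observer with motor noise, and
    cosine-tuned Poisson neurons with uncertainty-dependent off-direction
    gain) with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
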