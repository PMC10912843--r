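Package: dynstates
Title: Hidden Markov Model Analysis of Brain-State Dynamics in ROI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits group-level hidden Markov models with multivariate Gaussian
    emissions to multi-subject region-of-interest (ROI) BOLD time series,
    decodes per-subject brain-state sequences, and derives the temporal
    dynamics of the recovered states: fractional occupancy, mean lifetime,
    mean interval time, switching rate and the state transition probability
    matrix. Includes group inference (two-sample t tests with false discovery
    rate correction, label-permutation tests on transition probabilities,
    covariate-adjusted Spearman correlation with cognitive scores), a
    synthetic-cohort generator with known ground truth for validation, model
    order selection via BIC and state-occupancy degeneracy checks, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
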