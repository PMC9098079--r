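Package: ribomaint
Title: Growth Laws with Ribosome Maintenance and Protein Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the first bacterial growth law when protein
    degradation is not negligible. Implements the standard active-ribosome
    model, a degradation-only model, and a combined model in which a fraction
    of bound ribosomes performs maintenance synthesis that balances protein
    turnover, together with the constant-ratio ansatz linking the active
    fraction at null growth to ribosome allocation data. Includes estimators
    of mean protein degradation rates from pulse-chase decay curves
    (single-exponential, two-class and three-class mixture fits, with
    quantification of the Jensen underestimation bias), a saturated
    (linear-then-constant) breakpoint regression, growth-law regression
    utilities, and synthetic-data generators with known ground truth for
    validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
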