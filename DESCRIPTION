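Package: stratadjust
Title: Covariate Adjustment for Continuous Stratification Variables in
    Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation machinery for evaluating covariate-adjustment
    strategies in randomised trials where a continuous prognostic variable
    has been categorised for stratified randomisation. Generates trial
    datasets with stratified permuted-block randomisation, linear and
    non-linear covariate-outcome relationships, and missing-at-random
    outcomes; estimates treatment effects by linear or logistic regression
    with no adjustment, adjustment for the randomisation categories, or
    adjustment for the underlying continuous covariate (linear, two-term
    fractional polynomial, or restricted cubic spline); supports
    complete-case analysis, multiple imputation with Rubin's rules, the
    Cochran-Mantel-Haenszel common odds ratio, and standardised
    (g-computation) risk differences; and aggregates replications into
    bias, empirical SE, coverage and rejection-rate performance measures
    with Monte Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
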