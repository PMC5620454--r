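Package: psemult
Title: Planning and Estimation for Multiplier-Method Population Size
    Estimation with Respondent-Driven Sampling Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing multiplier-method population
    size estimation studies (service multiplier and unique-object multiplier)
    in which the proportion is measured by a respondent-driven sampling (RDS)
    survey. Provides the ratio point estimate M/P, a delta-method variance
    that combines Poisson uncertainty in the count M with design-effected
    sampling uncertainty in the proportion P, sample-size formulas with
    design effect and finite-population correction, confidence-interval-width
    versus sample-size planning curves over grids of proportions and design
    effects, a plausible-population-range helper from census and prevalence
    figures, and Monte-Carlo machinery that validates the analytic standard
    errors and interval coverage under the assumed data-generating process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
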