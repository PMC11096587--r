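Package: t2dmarkov
Title: Multistate Markov Forecasting of Type 2 Diabetes Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annual-cycle multistate Markov cohort model for projecting type 2
    diabetes prevalence from demographic projections and risk-factor
    (obesity, smoking) prevalence trends. Includes an illness-death model for
    back-calculating diabetes incidence and excess case fatality from
    cross-sectional prevalence and all-cause mortality, Levin attributable
    fractions for partitioning risk-factor overlap, pooled OLS trend
    projection of risk factors, policy scenarios on the obesity path,
    extreme-value (all-minimum / all-maximum) sensitivity bounds, validation
    against an observed prevalence series, and a synthetic-data generator
    emulating telephone-survey prevalence panels and cohort population
    projections. Ships age-by-sex fixtures for the Brazilian population and
    risk-factor prevalences 2006-2036.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
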