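Package: ageburden
Title: Ageing-Burden Metrics for Populations Aged 70 and Over
Version: 0.1.0
Authors@R:
    person("ageburden", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying death and disability burden in older
    adults from long-format burden-of-disease estimate tables. Builds
    abridged period life tables and extracts remaining life expectancy at
    age 70 (LE-70) and the probability of death between ages 70 and 90
    (20q70); computes comorbidity-adjusted years lived with disability,
    Sullivan-method healthy life expectancy at age 70 (HALE-70), and the
    proportion of remaining years spent in ill health (PYIH-70); attributes
    changes in 20q70 to cause-specific mortality trends by symmetric
    stepwise-replacement decomposition; performs categorical
    comparative-risk computations (population attributable fractions,
    summary exposure values, annualised rates of change); fits log-space
    cubic-spline epidemiological-transition curves against development
    covariates with observed-to-expected ratios; summarises input-data
    coverage; and propagates draw-level uncertainty through any pipeline
    stage. A synthetic data generator with known ground truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
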