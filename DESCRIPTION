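Package: zbmeta
Title: Bayesian Three-Level Meta-Regression of Obesity-Prevention Trials on the zBMI Scale
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to synthesise randomised trials of childhood obesity prevention
    interventions on a common outcome scale (BMI z-score) and to relate intervention
    effectiveness to coded intervention, trial and time-point characteristics. Provides
    mapping of unstandardised BMI, BMI percentile and overweight/obesity prevalence
    summaries onto the zBMI scale via LMS growth references; deterministic coding rules
    for follow-up categorisation, time-point selection and duration dichotomisation;
    collinearity and concordance screening of binary indicators; a three-level Bayesian
    meta-regression with multi-arm/multi-follow-up within-trial covariance, random or
    fixed intervention effects and interaction terms, fitted by a blocked Gibbs sampler;
    stochastic search variable selection (SSVS) over candidate interactions; exhaustive
    profiling of plausible indicator combinations; and a synthetic trial generator with
    known truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    rjags,
    withr
Config/testthat/edition: 3
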