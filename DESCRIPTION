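Package: adipofrac
Title: Body Adiposity Scoring and Population Attributable Fractions for
    Obesity-Related Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the body mass index (BMI) with the CUN-BAE
    anthropometric estimator of percent body fat in adult cohorts: scoring and
    obesity classification under both schemes, agreement statistics (Pearson
    R-squared, Cohen's kappa with an asymptotic 95% confidence interval),
    per-category crude and covariate-adjusted odds ratios for hypertension and
    type 2 diabetes, and the population attributable fraction by Miettinen's
    case-load formula. Includes a seeded generator of synthetic two-sex adult
    cohorts with logistic outcome models, and bundled summary tables from a
    cross-sectional study of 3888 Spanish adults for summary-level re-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
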