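Package: lymphoscore
Title: Percentile-Based Immune Cell Scores and Prognostic Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts regional tumor immune-cell densities (CD3+ and CD8+ T
    cells, CD20+ B cells, CD138+ plasma cells, measured in the tumor center
    and at the invasive margin) into percentile-based T cell and B
    cell/plasma cell scores with tertile stratification, and analyses their
    prognostic value: chi-square association tables against
    clinicopathological factors, tie-corrected Spearman correlation
    matrices, Kaplan-Meier curves with log-rank tests, and univariable and
    multivariable Cox proportional-hazards models with ordinal trend tests
    for cancer-specific and overall survival. Includes a seeded synthetic
    cohort generator (Gaussian copula densities with target Spearman
    correlations, configurable covariate marginals, cause-specific
    proportional-hazards event times with administrative censoring) so the
    whole pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
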