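Package: cohorteq
Title: Post-Hoc Equalization of Case/Control Cohorts in Tabular Biomedical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Balances case/control subpopulations in rectangular biomedical
    datasets after collection. Loads CSV or XLSX tables, infers variable types,
    imputes missing values with type-aware rules (mode for categorical
    variables; normality-gated mean or median for continuous variables),
    selects and runs the appropriate hypothesis test per variable (chi-square
    with continuity correction or Fisher's exact test; t-test or Mann-Whitney
    U; ANOVA with Tukey's HSD or Kruskal-Wallis with Dunn's post hoc), and
    equalizes subpopulation sizes and covariate proportions by seeded,
    impact-score-driven subsampling with protected samples and a minimum
    subpopulation size safeguard. Produces an integrity-checked before/after
    text report and a token-cost estimate for language-model processing of the
    table. Includes a seeded synthetic cohort generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
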