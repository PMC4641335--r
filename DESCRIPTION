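Package: semas
Title: Scoring and Psychometric Validation of the SeMaS Self-Management Screening Instrument
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A table-driven scoring engine for the Self-Management Screening
    questionnaire (SeMaS), a 27-item generic instrument that detects
    patient-level barriers to chronic-disease self-management. Provides
    declarative instrument definitions (response scales, construct item sets,
    barrier category rules), item recoding with missing-data policies,
    construct sum scores and no/minor/major barrier categorisation, coping
    style and locus-of-control resolution, a per-respondent graphic profile
    (text and SVG), and the full psychometric validation pipeline: criterion
    validity via positive and negative predictive values, internal consistency
    via Cronbach's alpha, normality-guarded Pearson/Spearman correlations, a
    univariate ANOVA screen, and forced-entry multivariate regression against
    the PAM-13 patient activation score. A synthetic-cohort generator with
    correlated latent traits, graded-threshold item responses, a criterion
    channel and item-level missingness makes the whole pipeline exercisable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
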