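Package: dentage
Title: Dental Age Estimation from Demirjian Tooth-Development Stages
Version: 0.1.0
Authors@R:
    person("Dentage", "Maintainers", email = "maintainers@dentage.example", role = c("aut", "cre"))
Description: Tools for dental maturity scoring and age estimation in
    children from staged radiographs of the seven left mandibular
    permanent teeth (Demirjian 8-stage system). Converts per-tooth stage
    ratings into a 0-100 maturity score, maps scores to dental age under
    interchangeable population standards (monotone lookup tables or
    polynomial calibration curves), fits linear and cubic age-prediction
    models by least squares, and ships Saudi reference prediction tables
    with refit cubic models. Includes the full method-comparison pipeline
    (dental-age minus chronological-age summaries by 1-year age group,
    paired t-tests, one-way ANOVA, Scheffe post hoc contrasts and
    homogeneous subsets, Cronbach's alpha for rater reliability), a
    synthetic cohort simulator for end-to-end validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
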