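Package: urocomp
Title: Non-Invasive and Invasive Urethral Compliance Estimation with a
    Biophysical Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies urethral compliance two ways: non-invasively as the
    slope of ultrasound-measured anteroposterior urethral diameter versus
    urinary flow rate (the UFD method), and invasively as the slope of
    cavity volume versus intraluminal pressure, with volumes reconstructed
    from injected air via Boyle's law (the Jesus method).  Ships a seeded
    biophysical synthetic-data generator (linear-elastic tube law, linear
    pressure-flow relation, isothermal gas inflation of a sealed segment)
    so every estimator is validatable by parameter recovery, plus the
    statistical layer used to compare the methods: normality-routed group
    comparisons (Shapiro-Wilk, exact Mann-Whitney, Student's t), Spearman
    correlation with exact small-sample p-values, Bland-Altman agreement,
    and equivalence-trial sample-size design, all orchestrated by a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
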