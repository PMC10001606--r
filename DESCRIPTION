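Package: greyrel
Title: Grey Relational Analysis and Intervention Regression for Annual Health Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ranking candidate risk factors of an annual
    health-outcome series by their degree of grey incidence. Implements
    Deng's degree of grey incidence together with the absolute, relative
    and two synthetic (SDGRA, SSGRA) degrees, sequence image operators
    (mean, initial-value and zero-start normalisation), one-year lag
    alignment, and per-model factor ranking with shared-rank tie notation.
    A companion regression stage fits ordinary least squares with an
    intervention dummy, case-resampling bootstrap standard errors and a
    Ramsey RESET specification diagnostic. A seed-reproducible synthetic
    panel generator emulates a two-decade sex-stratified mortality panel
    (smoking rate, physician density, income per capita) around a policy
    intervention, so the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
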