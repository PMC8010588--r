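Package: famagg
Title: Familial Aggregation Analysis of Binary Diagnoses in Multigeneration Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate familial aggregation of a binary lifetime
    diagnosis (modelled on registry-coded syncope, ICD-10 R55.9) from a
    multigeneration person registry. Extracts double-entered relative pairs of
    graded genetic resemblance (twins, full siblings, half-siblings, first
    cousins) from parent links, estimates twin zygosity composition by the
    Weinberg differential method, and quantifies familial risk via incidence
    rates with person-years at risk, incidence rate ratios, crude and
    covariate-adjusted familial odds ratios, tetrachoric correlations,
    Kaplan-Meier syncope-free survival with log-rank tests, and a
    genetic-resemblance interaction model. Includes a liability-threshold
    synthetic-registry simulator with known familial correlation structure so
    every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, survival
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
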