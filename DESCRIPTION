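Package: hazfn
Title: Societal Risk Analysis of Hazardous Materials Transportation Accidents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characteristic, cause and severity analysis of hazardous
    materials transportation accident (HTA) records. Builds F-N societal-risk
    curves (cumulative frequency of accidents with N or more fatalities),
    quantifies the uncertainty of the log-log slope by fitting normal,
    adjusted-normal and power-law models, draws 95 percent confidence bands,
    and classifies curves against ALARP ("as low as reasonably practicable")
    criterion lines. Also provides severity-level classification of accident
    records, descriptive temporal and categorical summaries, a CHAID
    (chi-squared automatic interaction detection) decision tree for
    cause-consequence analysis with confusion-matrix evaluation, k-means
    clustering of regional socio-economic profiles with ANOVA and Tukey HSD
    validation, and a synthetic accident-record generator for testing and
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
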