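Package: biasbound
Title: E-Values and Joint Bounding Factors for Unmeasured Confounding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative bias analysis for observational exposure-outcome
    associations on the relative-risk scale. Pools study-level estimates with
    a restricted-maximum-likelihood random-effects meta-analysis, computes
    E-values for point estimates and confidence limits, and uses the joint
    bounding factor to quantify how much of an observed association a
    hypothetical unmeasured confounder of given strength could explain,
    including total-confounding thresholds and bounding-curve coordinates.
    Includes effect-measure conversions (odds and hazard ratios and
    correlations onto the risk-ratio scale) and synthetic-data generators
    (study-level estimates with between-study heterogeneity, and
    individual-level cohorts with a binary unmeasured confounder) so every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
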