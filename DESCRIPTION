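Package: mrscore
Title: Morphometric Risk Scores for Case-Control Brain Imaging Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-subject morphometric risk scores (MRS) from
    regional brain morphometry: each of 75 bilaterally averaged regions
    (34 cortical thickness, 34 cortical surface area, 7 subcortical
    volumes) is deconfounded for age, sex and the metric-appropriate
    global measure, z-rescaled, harmonized across acquisition sites with
    empirical-Bayes (ComBat) batch adjustment, and aggregated against
    meta-analytic effect-size weights under a sign-congruency rule.
    Includes diagnosis-specific weight construction (shared first
    principal component, unique-variance residuals, unit-weight
    negative control), covariate-adjusted group inference with IQR
    outlier labeling, dependent-correlation comparison of competing
    scores, spatial spin/shuffle permutation nulls for parcellated
    effect-size maps, analytic power for two-sample designs, an
    out-of-distribution logistic classifier, and a synthetic-cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr
Config/testthat/edition: 3
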