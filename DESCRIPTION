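Package: dtmr
Title: Drug-Target and Nonlinear Mendelian Randomization with
    Individual-Level Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for drug-target Mendelian randomization analyses of
    individual-level cohort data: selection of genetic instruments in a
    cis gene region from a covariate-adjusted exposure GWAS, LD clumping,
    weighted genetic scores, causal effect estimation for binary outcomes
    by the ratio-of-coefficients (Wald) method with delta-method
    confidence intervals, and nonlinear Mendelian randomization by
    residual-based and doubly-ranked stratification with Cochran's Q
    heterogeneity and quadratic-trend tests.  Includes a seeded synthetic
    cohort generator emulating a biobank-style data structure (genotype
    dosages, a continuous exposure biomarker, correlated lipid
    biomarkers, and binary disease outcomes) so that the whole pipeline
    can be exercised and calibrated without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
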