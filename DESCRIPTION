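Package: mrforge
Title: Two-Sample Mendelian Randomization with Sensitivity, Multivariable
    and Colocalization Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: harmonization of exposure and outcome effect alleles, genetic
    instrument selection by significance threshold and greedy linkage-
    disequilibrium clumping (including gene-specific cis instruments with
    tiered significance fallback), the Wald ratio, inverse-variance weighted
    (fixed and multiplicative random effects), MR-Egger, weighted median and
    weighted mode estimators with an automatic dispatch rule, Steiger
    directionality filtering, a Slope-Hunter-style collider-bias slope
    correction, multivariable inverse-variance weighted MR, approximate-Bayes-
    factor colocalization with five-hypothesis posteriors, a robustness
    checklist orchestrating sensitivity grids and reverse MR, and a synthetic
    GWAS summary-statistics generator with known ground truth for calibration
    and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
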