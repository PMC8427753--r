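Package: abza
Title: Anterior Borderzone Angle Collateral Grading and Prognostic Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative grading of leptomeningeal collateral circulation
    from single-projection digital subtraction angiography via the anterior
    borderzone angle (ABZA): geometric measurement of the angle between the
    sagittal-sinus midline and the line joining the projected internal
    carotid bifurcation to the anterior/middle cerebral artery pial
    borderzone center, normalization against the 23.0 degree upper normal
    reference limit, and binning into a 0-4 collateral score. Includes the
    downstream prognostic pipeline for endovascular-treatment cohorts
    (univariate comparisons, enter-method logistic regression with odds
    ratios and Wald intervals, ROC analysis with Youden-index cutoff
    selection, contingency-table diagnostics, inter-rater reliability) and
    a synthetic-cohort generator with calibrated outcome prevalence for
    end-to-end testing and parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
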