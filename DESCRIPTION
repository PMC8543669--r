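Package: eyecode
Title: FASD Eye Code Scoring and Diagnostic Accuracy Toolkit
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the FASD Eye Code, a four-category ophthalmological
    scoring rubric (best corrected visual acuity, cycloplegic refraction,
    strabismus and binocular function, ocular structural abnormalities) used
    as a complementary aid when a fetal alcohol spectrum disorder diagnosis
    is suspected. Each category is ranked 1-4 under a configurable,
    JSON-encoded band rubric; totals (4-16) are classified against a cut-off.
    Ships the full diagnostic-accuracy toolchain for evaluating the code
    against comparison groups: confusion-based indices and likelihood ratios
    at every cut-off, empirical ROC curves, Mann-Whitney AUC with DeLong and
    stratified-bootstrap confidence intervals, greedy minimum-maximal-t
    case-control matching, and a paired Wilcoxon signed-rank comparison of
    childhood versus young-adult totals. A calibrated synthetic-cohort
    simulator reproduces published group-level score summaries so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
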