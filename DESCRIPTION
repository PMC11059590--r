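Package: glomRPS
Title: Glomerular Morphometrics and Rule-Based RPS Classification for
    Diabetic Nephropathy
Version: 0.1.0
Authors@R:
    person("glomRPS", "Developers", email = "glomrps@example.org",
           role = c("aut", "cre"))
Description: Quantifies glomerular morphologic features from labeled
    glomerulus images (tuft and mesangial areas, intrinsic cell counts,
    densities and ratios), aggregates them to patient level, and applies a
    rule-based Renal Pathology Society (RPS) classification of diabetic
    nephropathy driven by percent global glomerulosclerosis, presence of
    Kimmelstiel-Wilson lesions and ROC-derived mesangial cutoffs. Includes
    segmentation and classification evaluation metrics (confusion matrix,
    per-class accuracy/specificity/precision/recall/F1, Dice), agreement
    and prognostic statistics (Cohen's kappa, Spearman correlation, tests
    for comparing two dependent overlapping correlations, eGFR slope,
    time-averaged proteinuria, ESRD event accounting), and a synthetic-data
    module that generates labeled glomeruli, confusion-controlled
    predictions and longitudinal clinical cohorts so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
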