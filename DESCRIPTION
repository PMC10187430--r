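Package: evmarkers
Title: Discovery and Evaluation of Lineage-Specific Extracellular-Vesicle
    Protein Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for prioritizing and evaluating extracellular-vesicle
    (EV) surface-protein biomarkers from label-free proteomic quantification
    tables. Implements a multi-stage candidate funnel (presence filtering,
    lineage consensus, core-proteome and transmembrane-annotation
    intersection, common-EV subtraction, fold-change ranking), a
    kernel-smoothed ROC curve with the ROC-curve-length statistic and
    monotone/non-monotone marker classification, single-marker diagnostic
    inference (AUC with DeLong standard errors, fixed-specificity and
    fixed-sensitivity operating points, Youden index), and AIC-based
    exhaustive logistic panel selection with a linear combination score.
    Includes seeded synthetic-data generators with machine-readable ground
    truth for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
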