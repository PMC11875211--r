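Package: ctgdx
Title: Cardiotocography Cleaning, Feature Extraction and Diagnostic Accuracy Evaluation
Version: 0.1.0
Authors@R: person("ctgdx", "maintainers", email = "ctgdx@example.org", role = c("aut", "cre"))
Description: Tools for intrapartum cardiotocography (CTG) analysis: artifact
    removal and gap interpolation for 4 Hz fetal heart rate traces, extraction
    of the 30-minute pre-delivery analysis segment, a documented 44-element
    guideline-style feature vector (baseline, variability, accelerations,
    decelerations, uterine activity), neonatal asphyxia outcome labeling from
    Apgar scores and umbilical-artery pH, fusion of human rater panels with
    model scores, and diagnostic-accuracy evaluation (confusion matrices,
    sensitivity/specificity/precision/NPV/accuracy, likelihood ratios, ROC and
    AUC with a Hanley-McNeil significance test). Includes a seeded synthetic
    cohort generator so the full pipeline is exercisable without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
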