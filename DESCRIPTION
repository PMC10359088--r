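Package: oncoassign
Title: Interpretable Drug Assignment from Ex Vivo Drug-Sensitivity Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patient-centered precision-oncology methods that recommend one
    drug per patient from an ex-vivo drug-sensitivity screen and a biomarker
    matrix.  Implements optimal decision trees whose splits jointly select a
    biomarker (with an optional threshold for continuous markers) and a drug
    per branch by maximizing summed transformed benefit, and a soft-label
    multinomial lasso / grouped-lasso regression on probabilistic drug votes.
    Includes per-drug centering of log-IC50 values (IC50*), an evaluation
    protocol with Oracle reference, per-patient regret, seeded k-fold
    cross-validation and intragroup rank-sum validation, seeded synthetic
    cohort generators with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
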