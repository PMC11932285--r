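Package: urinmr
Title: Urinary NMR Metabolomics: Internal-Standard Quantification,
    PLS-DA with Repeated Double Cross-Validation and Stability-Based
    Variable Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for biomarker discovery from one-dimensional 1H-NMR
    urine spectra in two-group (exposed vs control) designs. Converts
    processed spectra into metabolite concentrations by per-proton
    integral normalization against a TSP internal standard followed by
    creatinine normalization; fits two-class PLS-DA models validated by
    repeated double (nested) cross-validation with sensitivity,
    specificity and accuracy figures of merit; selects discriminant
    metabolites whose first-canonical-variate weights keep a consistent
    sign across all cross-validation models and whose confidence
    interval excludes zero; and runs a normality- and
    homoscedasticity-routed univariate branch (Student's t or Wilcoxon
    rank-sum). A synthetic-data module generates group-structured
    concentration tables and Lorentzian urine-like spectra with known
    ground truth so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
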