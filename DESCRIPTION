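Package: petdosim
Title: Translating Preclinical PET Dosimetry to Clinical Dose Predictions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for estimating human radiation doses of fluorine-18 PET
    radiotracers from rodent whole-body imaging. Computes residence times
    (time-integrated activity coefficients) from organ time-activity curves by
    trapezoidal integration with a physical-decay tail, applies rat-to-human
    organ-mass normalisation, evaluates MIRD-schema absorbed and effective
    doses from a phantom S-value matrix, and quantifies the bias of predicted
    clinical doses against measured clinical reference doses, including
    regression-slope bias, Bland-Altman agreement, reconstruction-method
    comparison and a simplified underestimation correction factor. A seeded
    synthetic-data generator emulates kidney-dominant peptide kinetics so the
    whole pipeline is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
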