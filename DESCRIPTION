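Package: autofif
Title: Automated Field-in-Field Whole-Brain Radiotherapy Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automates field-in-field (FiF) whole-brain radiotherapy (WBRT)
    forward planning around a treatment planning system's Auto-FiF function.
    Extracts geometric features from anatomical structure sets (DICOM RTSTRUCT
    or a plain-text fixture format), predicts patient-specific Auto-FiF
    hyperparameters (target coverage priority, number of subfields, minimum
    segment MU and area) with three small multi-class neural network heads,
    attributes predictions to features with integrated gradients, evaluates
    plans through dose-volume histogram metrics (D1%, D95%, D99%, mean organ
    dose) with D95% normalization, and closes the loop by converting
    natural-language plan critiques into a staged localized hyperparameter
    re-search with revert fallback. A synthetic surrogate plan engine and an
    anatomy phantom generator make every stage testable without clinical data
    or a commercial planning system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
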