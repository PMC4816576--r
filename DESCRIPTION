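Package: errclass
Title: Single-Trial Classification of Response Errors from Error-Related EEG Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for classifying response
    correctness (error vs. correct) from single-trial, response-locked EEG.
    Generates synthetic multi-channel epochs carrying an error negativity
    (Ne/ERN) and an error positivity (Pe), preprocesses them (FIR band-pass,
    linked-mastoid re-reference, statistical artifact rejection), quantifies
    the components as windowed mean amplitudes, and classifies single trials
    with a radial-basis-function support vector machine using nested grid
    search, stratified 10-fold cross-validation, cross-task transfer, and
    permutation-based significance, with per-subject report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
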