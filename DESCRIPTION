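Package: etriage
Title: Epsilon-Refusal Triage Rules for Selective Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Selective classification with a reject option: fit and apply
    triage rules that refuse to label a controlled fraction epsilon of
    items so that precision on the labelled subset exceeds the precision
    of the Bayes classifier.  Provides the oracle rule for known
    conditional class probabilities, a soft-max thresholding heuristic
    for estimated scores, precision-coverage curves, a per-class
    minimum-count filter, Gaussian-mixture synthetic models with exact
    Bayes and triage risks, and a small command-line interface for
    fitting and applying rules to delimited score tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
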