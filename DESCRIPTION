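Package: bfdna
Title: Base-Frequency DNA Encoding and BiLSTM Enhancer Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Numeric encoding schemes for DNA sequences (integer, atomic
    number, electron-ion interaction potential, and the dynamic
    base-frequency scheme BFDNA), together with a bidirectional LSTM
    classifier stack for enhancer sequence classification, a nine-metric
    confusion-matrix evaluation suite (accuracy, precision, recall,
    F1-score, CSI, G-mean, MCC, Cohen's kappa, micro/macro ROC-AUC), a
    synthetic labeled-sequence generator with class-specific base
    composition, FASTA/label-table input-output, and a command-line
    interface tying the stages into a reproducible workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
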