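Package: ecgbench
Title: Benchmarking Single-Lead ECG Arrhythmia Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A configurable benchmarking pipeline for arrhythmia detection
    from single-lead ECG. Unifies heterogeneous dataset annotations through
    a label dictionary, reads beat-level (WFDB-style waveform + annotation)
    and recording-level datasets, segments recordings into heartbeats,
    rhythm episodes, sliding windows or full sequences with explicit
    label-assignment rules, trains four 1-D neural architectures (CNN,
    ResNet, GRUAttNet, RTA-CNN) plus a majority-class baseline on a small
    built-in neural-network engine, and evaluates them under patient-aware
    cross-validation schemes, including stratified-group inter-patient
    k-fold. Ships an annotated synthetic single-lead ECG generator so the
    whole pipeline runs end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    optparse
Config/testthat/edition: 3
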