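Package: barEEG
Title: Brain-Area Recombination Augmentation for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Channel-level data augmentation for two-class motor-imagery
    electroencephalography (EEG). Implements brain-area recombination (BAR):
    epochs are split into left- and right-hemisphere channel blocks using the
    10-20 montage parity convention, and artificial trials are built as the
    per-class cartesian product of right and left half-trials, within one
    subject or across a cohort. Ships the comparison augmenters (time-axis
    flipping, SNR-controlled additive Gaussian noise in two expansion-ratio
    versions), a Butterworth band-pass preprocessing and epoching step, a
    common-spatial-patterns (CSP) plus support-vector-machine baseline
    classifier, intra-subject and adaptive (pre-train/fine-tune) evaluation
    schemas with paired t-test reporting, and a seeded generator of
    hemisphere-lateralized event-related-desynchronization (ERD) signals for
    download-free testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
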