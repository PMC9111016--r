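Package: earaad
Title: Auditory Attention Analysis for Around-the-Ear EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing selective auditory attention in multichannel
    around-the-ear EEG recorded during competing-speaker listening. Implements
    backward (stimulus-reconstruction) decoding of the attended speech envelope
    with Tikhonov-regularised lagged regression, nested and leave-one-out
    cross-validation over a time-lag/regularisation hyperparameter grid,
    intersubject correlation via correlated component analysis with
    circular-shift surrogate nulls and ROC classification of the attended
    direction, multitaper spectral entropy and alpha-power time courses, and
    artifact subspace reconstruction. Includes a synthetic competing-speaker
    cohort generator with speech-like envelopes, lagged-kernel cortical
    responses, shared stimulus-locked components, 1/f background noise,
    artifact bursts and slow alpha drift, plus an end-to-end reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
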