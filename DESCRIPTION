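Package: ecgsonify
Title: Polyphonic Parameter-Mapping Sonification of Multi-Channel ECG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts six-channel frontal-plane electrocardiogram (ECG)
    recordings into polyphonic audio by parameter-mapping sonification:
    each lead drives the amplitude and pitch of a time-variant oscillator
    tuned to a note of the D minor scale, with a fixed harmonic set and a
    linear loudness-compensation ramp. Includes a reader/writer for WFDB
    and delimited-text ECG records, a synthetic six-lead ECG generator
    covering normal rhythm, ST-elevation myocardial infarction, premature
    ventricular contractions, bigeminy and atrial fibrillation, spectral
    validation utilities (FFT peak estimation, harmonic amplitude ratios,
    pitch tracking), and the classification statistics used to score
    blinded observer studies (per-observer accuracy, group summaries,
    confusion matrices, one-tailed two-sample t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
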