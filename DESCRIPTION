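Package: hapticEEG
Title: EEG Emotion Recognition Under Wearable Haptic Vibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for four-class EEG emotion recognition with
    and without wearable vibrotactile (haptic) stimulation. Provides a
    synthetic multichannel EEG experiment generator with class-dependent
    band power and a configurable haptic separation gain, two haptic
    vibration schedulers (fixed-rhythm and volume-adaptive), a standard
    preprocessing chain (resampling, zero-phase band filtering, seeded ICA
    artifact removal, common average re-referencing, session segmentation),
    five-band power spectral density and differential entropy features with
    hemispheric-asymmetry (DASM) and frontal-posterior (DCAU) pair
    differences, per-subject linear-SVM cross-validated evaluation, paired
    haptic versus non-haptic statistics with growth-rate tables, Morlet
    wavelet time-frequency summaries, and baseline-subtracted differential
    entropy scalp topographies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
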