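Package: cprsuppress
Title: Condition-Based Suppression of CPR Chest-Compression Artifacts in ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for removing cardiopulmonary-resuscitation (CPR)
    chest-compression artifacts from single-channel ECG segments so that
    automated shock/no-shock rhythm analysis can run while compressions
    continue. Implements a condition-based cascade of narrow stop-band
    filters whose centre frequencies track the compression fundamental
    (1-3 Hz) and its harmonics, gated by spectral rules that protect the
    3-6 Hz dynamics of shockable rhythms (ventricular fibrillation, rapid
    ventricular tachycardia). Includes Welch power-spectral-density peak
    analysis, wavelet baseline removal, an additive corruption model that
    mixes artifacts into clean ECG at a controlled signal-to-noise ratio,
    seeded synthetic rhythm and compression-artifact generators, and
    evaluation metrics (SNR improvement, PSD correlation, band-power
    threshold calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
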