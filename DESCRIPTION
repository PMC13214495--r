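Package: hearsim
Title: Offline Hearing-Loss and Hearing-Aid Simulation with SPL Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Renders calibrated "normal", "unaided hearing loss" and "aided"
    versions of an audio signal from a two-ear audiogram. Unaided loss is
    simulated as per-ear, per-band attenuation equal to threshold elevation
    through a zero-phase STFT filterbank; the aided path prescribes
    multi-channel wide dynamic range compression (a DSL-style half-gain rule
    by default, pluggable) applied before the impaired-ear filter. Listening
    environments cover speech in quiet, speech in noise at an adjustable
    signal-to-noise ratio, talker distance by the inverse square law, and
    music. A calibration subsystem maps digital RMS to dB SPL and produces
    Speechmap-style LTASS reports with dynamic speech range for verification.
    Includes seeded synthetic fixtures (speech-shaped modulated noise, babble,
    tones, arpeggiated music) so every analysis is self-contained, plus WAV
    input/output and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
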