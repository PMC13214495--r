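# hearsim

Offline hearing-loss and hearing-aid simulation for R, with SPL calibration
and Speechmap-style verification.

Family members, students and clinicians rarely have an accurate sense of
what a specific hearing loss *sounds like*. hearsim takes an audio signal
and a two-ear audiogram and renders three calibrated versions of it — the
**normal** reference, the **unaided** loss, and the **aided** result heard
through a simulated hearing aid — across four listening environments:
speech in quiet, speech in noise at an adjustable SNR, speech at a talker
distance, and music. A calibration subsystem anchors digital RMS to dB SPL
and produces LTASS (long-term average speech spectrum) reports with the
p30–p99 dynamic speech range, so every render can be verified the way a
real-ear Speechmap verifies a fitting.

## The models

**Unaided loss** is threshold-elevation attenuation: per ear, per band,

    gain_dB(f) = −HL(f)

with HL interpolated linearly in dB vs log₂(frequency) from the audiogram
and applied through a zero-phase, perfect-reconstruction STFT filterbank
(sqrt-Hann windows, 75% overlap). A flat 0 dB HL audiogram is an exact
passthrough. No recruitment or distortion is modeled — the simulation is
deliberately audibility-only.

**Aided** renders run wide dynamic range compression (6 channels, octave
edges from 250 Hz, attack 5 ms / release 100 ms) before the impaired-ear
filter. The default prescription is a DSL-style half-gain rule: per
channel, G65 = clamp(HL/2, 0, 50) dB, CR = clamp(1 + HL/100, 1, 3),
kneepoint 40 dB SPL, ceiling 105 dB SPL. The static I/O curve is slope 1
below the knee, 1/CR above, anchored through (65, 65 + G65). Consequence,
and the point of the demonstration: for any loss, `unaided RMS < aided RMS
< normal RMS` — hearing aids improve audibility but do not restore normal
hearing.

**Environments**: noise mixed at an exact full-band-RMS SNR; distance by
the inverse square law, −20·log₁₀(d/1 m) dB (12 ft ⇒ −11.263 dB); ambient
noise is not distance-scaled, so SNR degrades with distance.

All test material is synthesized by formula (speech-shaped 4 Hz-modulated
noise, babble, tones, an arpeggiated music stand-in), seeded and exactly
reproducible.

## Worked example

```r
library(hearsim)
calib <- default_calibration()        # 63.5 dB SPL anchor at volume 20
ag <- audiogram_preset("sloping_snhl")
ag
#> <audiogram> dB HL thresholds
#>   left  250:15  500:20  1000:30  2000:45  4000:60  8000:70
#>   right 250:15  500:20  1000:30  2000:45  4000:60  8000:70

jobs <- lapply(c("normal", "unaided", "aided"), function(m)
  render(render_job(mode = m, ag = ag, duration = 1, rate = 32000, seed = 1)))
names(jobs) <- c("normal", "unaided", "aided")
compare_report(jobs, calib)$summary
#> # A tibble: 3 × 6
#>   label   mode    env   spl_db snr_db delta_db
#> 1 normal  normal  quiet   65       NA     0
#> 2 unaided unaided quiet   47.0     NA   -18.0
#> 3 aided   aided   quiet   56.2     NA    -8.77
```

Conversational speech at 65 dB SPL drops to 47 dB SPL through this sloping
loss; the simulated aid recovers about 9 dB of audibility but stays well
below the normal reference — the ordering the tool exists to demonstrate.
Verification of the unaided chain against the audiogram:

```r
src <- set_spl(conversational_fixture(6, 32000), 63.5, calib)
verify_chain(src, ag, "unaided")$checks
#> 1 input level conversational (62-65 dB SPL)                63.5   [62, 65] TRUE
#> 2 per-band attenuation matches hearing level (max error)    0.542 <= 2    TRUE
```

`autoplot(compute_ltass(src, calib))` draws the Speechmap-style LTASS with
its dynamic-range ribbon.

## Command line

```sh
Rscript inst/cli/hearsim.R render --fixture speech_shaped --preset sloping_snhl \
    --mode aided --env noise --snr 5 --seed 1 --out aided.wav
Rscript inst/cli/hearsim.R compare --preset sloping_snhl --env quiet
Rscript inst/cli/hearsim.R verify --preset sloping_snhl --mode unaided --out-csv v.csv
```

Subcommands: `render`, `fixtures`, `verify`, `compare`, `presets`. WAV in
(PCM16/24, float32) and out (float32 default); audiograms as JSON
(`{"left": {"250": 15, ...}, "right": {...}}`); every render writes a JSON
sidecar with settings, measured SPL and clip count.

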