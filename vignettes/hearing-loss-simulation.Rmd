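---
title: "Simulating hearing loss, hearing aids and listening environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating hearing loss, hearing aids and listening environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hearsim renders what a sound would be like for a listener with a given
audiogram: a *normal* reference, an *unaided* hearing-loss version, and an
*aided* version heard through a simulated hearing aid. It is intended for
counseling-style demonstrations — letting communication partners, students
and clinicians hear a specific loss — and for verifying, with Speechmap-style
measurements, that the rendered levels are what the model says they should
be. This vignette explains the models, the parameters that matter, the
numerical choices, and what the synthetic fixtures do and do not tell you
about real speech.

## The hearing-loss model

An audiogram gives per-ear thresholds in dB HL at the standard audiometric
frequencies (250–8000 Hz octaves required, inter-octaves optional). The
unaided simulation is pure threshold-elevation attenuation:

$$ \text{gain}_{\mathrm{dB}}(f) = -\mathrm{HL}(f) $$

interpolated linearly in dB against log2(frequency), flat beyond the
outermost audiogram points. That is the whole model: intensity decrements
per frequency band, applied independently per ear. It deliberately does
*not* model loudness recruitment, spectral smearing, temporal deficits or
tinnitus — a sensorineural loss also distorts, and listeners with normal
hearing should know that what they hear is the audibility component only.
A flat 0 dB HL audiogram is therefore an exact passthrough, which anchors
the whole test suite.

Attenuation is applied by a zero-phase STFT filterbank: square-root Hann
analysis and synthesis windows, 75% overlap, FFT size 2048 at rates ≥ 32 kHz
(1024 below), which satisfies the constant-overlap-add identity exactly
(window-product sum = 2). Per-bin gains are interpolated from the band gains
in dB vs log-frequency; the DC bin takes the lowest band's gain. Because the
bin gains are real and positive the filter is zero-phase, and the framing is
aligned so there is no residual latency.

## The hearing-aid model

The aided path is wide dynamic range compression (WDRC) prescribed from the
audiogram, then passed through the impaired-ear attenuation — aided sound is
heard *through* the loss. Six compression channels with octave edges from
250 Hz (the top channel runs to Nyquist), attack 5 ms, release 100 ms —
typical commercial values.

Prescriptions are a pluggable registry. The default, `dsl_like_halfgain`,
is a DSL-style level-dependent rule kept deliberately simple and
self-contained, because published prescriptive coefficient tables are
proprietary: per channel with interpolated threshold HL,

* gain at 65 dB SPL input: `G65 = clamp(HL/2, 0, 50)` dB (the classic
  half-gain rule),
* compression ratio: `CR = clamp(1 + HL/100, 1, 3)`,
* lower kneepoint 40 dB SPL, output ceiling 105 dB SPL.

The static input/output curve is linear (slope 1) below the knee, slope
1/CR above it, continuous at the knee, anchored through (65, 65 + G65), and
hard-limited at the ceiling. This preserves the qualitative contract the
package exists to demonstrate: amplification improves audibility but does
not restore normal hearing, since half-gain under-compensates wherever
HL > 0. A faithful DSL v5.0 or NAL table can be registered later without
touching the engine.

### Numerical design of the compressor

Two choices here were driven by measurement, and are worth recording:

* **Band splitting** uses exact zero-phase filtering in the full-signal
  frequency domain — one FFT of the zero-padded signal, complementary
  raised-cosine masks (transitions of a sixth of an octave, at least 50 Hz)
  that sum to exactly 1 per bin, one inverse FFT per channel. An earlier
  implementation masked hopped STFT frames instead; modifying frames with
  sharp masks scatters a steady tone into neighbouring channels at
  frame-rate image frequencies around −35 dB, and a neighbouring channel
  applying 40+ dB of below-knee gain turns that into a 1–2 dB steady-state
  level error. The full-spectrum split has no frames, hence no images, and
  the channels reconstruct the input to machine precision.
* **Level detection**: the instantaneous band power is first averaged by a
  symmetric one-pole smoother at the attack time constant (an unbiased RMS
  estimate for steady tones), then tracked by the attack/release one-pole
  follower, and converted to dB SPL through the calibration map so the
  kneepoint has acoustic meaning. Without the pre-average, the asymmetric
  follower rides the 2f power ripple of a tone toward its peak and biases
  steady-state gains by over a decibel at 1 kHz.

With these choices, steady-state tone levels match the static curve within
0.04 dB across all channels over a 45–95 dB SPL sweep, and a step response
matches a sample-by-sample scalar reference implementation of the same
detector law to numerical precision.

No hearing-aid microphone or receiver bandwidth limit is imposed (flat to
Nyquist): any high-frequency deadness in aided music comes from the loss
filter itself, which is the effect being demonstrated.

## Listening environments

Four environments mirror the demonstration set: speech in quiet, speech in
noise, speech at a distance, and music.

* **Noise** is mixed at a requested SNR defined on full-band RMS of the
  overlapping segment; the speech component is left bit-identical and the
  noise is scaled, so the realized component SNR equals the request to
  machine precision. Noise longer than the speech is trimmed, never looped.
* **Distance** follows the inverse square law,
  `ΔL = −20·log10(d/d_ref)` dB with a 1 m free-field reference by default
  and feet converted at exactly 0.3048 m; doubling distance always costs
  6.0206 dB, and the demonstration distance of 12 ft is −11.263 dB re 1 m.
* When noise and distance are combined, the SNR is set at the reference
  distance and only the speech is then distance-attenuated: the noise is
  ambient, so the effective SNR at the listener degrades with distance —
  which is exactly why amplified speech at a distance still sounds quiet.
* No reverberation or air absorption is modeled; the environment layer is
  intensity-only, matching the rest of the engine.

Environments are applied before the profile stage, so all three profiles
hear the same sound field.

## Calibration and Speechmap-style verification

A `calibration_map` is an affine bridge between digital and acoustic level:
`level = offset + 20·log10(RMS) − attenuation(volume)`, with a volume
control attenuating 0.5 dB per step below the reference setting of 100.
The default map sets the offset (123.5 dB SPL at 0 dBFS RMS) so that the
packaged conversational fixture — speech-shaped noise at −20 dBFS RMS —
measures 63.5 dB SPL at the calibrated volume setting of 20, the center of
the 62–65 dB SPL conversational window the simulator is anchored to. No
per-frequency HL↔SPL transform is applied; the anchor is broadband RMS,
and since no hardware is in the loop the anchor is definitional.

`compute_ltass()` produces the verification display: Hann-windowed 125 ms
frames at 50% overlap, integrated into third-octave bands 125 Hz–8 kHz
(exact base-2 centers, ANSI nominal labels); the long-term level per band
is the dB of the mean band power, and the dynamic speech range is the
30th/99th percentile of the short-term band levels — common Speechmap
practice, chosen here as the artifact's own parameters since commercial
analyzers do not publish theirs. `verify_chain()` renders a chain and
checks it: conversational input level in window, identity spectrum for the
normal profile (±0.5 dB), per-band attenuation equal to the interpolated
HL (±2 dB mid-bands) for unaided, and aided band levels at or above
unaided wherever HL > 0.

## Synthetic fixtures: what they emulate and what they don't

All test material is generated by formula, seeded, and therefore exactly
reproducible — no recordings are distributed:

* `speech_shaped`: Gaussian noise shaped flat over 100–500 Hz with a
  −9 dB/octave rolloff above 500 Hz (and a steep low-cut below 100 Hz),
  amplitude-modulated at 4 Hz with depth 0.6. The spectrum emulates a
  long-term average speech spectrum and the modulation a syllabic envelope.
* `babble`: eight independent speech-shaped streams with randomized
  modulation phases, summed.
* `tone:<freq>`, `white`: calibration primitives.
* `music_tones`: an arpeggiated harmonic note cycle spanning 262–3520 Hz
  with 200 ms notes and three harmonics, standing in for instrumental
  music's wider register.

These fixtures have speech-like spectra and envelopes but no phonetic
structure, so passing tests demonstrate that *levels, spectra and dynamics*
are rendered correctly — they say nothing about intelligibility or perceived
sound quality of real recordings. That is the right scope: the engine's
claims are all at signal level.

Default study conditions used throughout the tests and the acceptance
script: conversational input at 65 dB SPL, the `sloping_snhl` preset
(250/500/1000/2000/4000/8000 Hz → 15/20/30/45/60/70 dB HL, symmetric — a
typical mild-sloping-to-severe presbycusis shape, registered as data and
trivially replaceable), demonstration SNR 5 dB, demonstration distance
12 ft. Analysis problem sizes are kept small but sufficient: 0.5–1 s
fixtures for filter checks, 6–8 s for LTASS statistics, 200 random
audiograms for the attenuation-fidelity sweep.

## Degenerate inputs, ties and tolerances

* Silent buffers cannot be level-measured or used as noise (errors, not
  NaNs); envelope powers are floored at 10⁻²⁰ before the dB conversion.
* Samples beyond ±1 after rendering are hard-clipped with a logged count;
  attenuation-dominated paths essentially never clip, aided paths may.
* Steady-state compressor levels are measured on the interior 50–90% of a
  tone buffer: an abruptly gated tone has broadband onset/offset skirts
  that any band filter rings on, and those edges are not "steady state".
* Audiogram interpolation evaluated exactly at an audiogram frequency
  returns that threshold; between points it is monotone (no overshoot) by
  construction of piecewise-linear interpolation.
* Stereo inputs to a render are averaged to mono before ear duplication:
  the simulator models one sound field heard by two (independent) ears.
* dB-scale test assertions use absolute tolerances throughout.

## Known limitations

* Audibility-only loss model (no recruitment/distortion), by design.
* The default prescription is DSL-*like*, not DSL v5.0; absolute aided
  levels should not be read as clinical targets.
* The calibration anchor is definitional — there is no acoustic hardware in
  the loop, so "dB SPL" means "dB SPL under the declared map".
* Third-octave analysis covers 125 Hz–8 kHz; content outside contributes to
  broadband RMS but not to band displays.
* Environments are anechoic and intensity-only.
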