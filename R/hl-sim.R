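#' Simulate unaided hearing loss
#'
#' Attenuation-only model: per ear, the gain at frequency f is minus the
#' interpolated hearing threshold, `gain_dB(f) = -HL(f)`, applied through
#' the zero-phase STFT filterbank. This reproduces decrements in intensity
#' across frequency bands; it deliberately models no loudness recruitment,
#' spectral smearing or other distortion. A flat 0 dB HL audiogram is an
#' exact passthrough.
#'
#' Mono input is duplicated onto both ear paths first; output is always
#' stereo (left, right), each ear filtered by its own audiogram side, so the
#' two channels are fully independent.
#'
#' @param x An `audio_buffer` (mono or stereo).
#' @param ag An `audiogram`.
#' @param spec Optional `filterbank_spec`.
#' @return A stereo `audio_buffer`.
#' @export
simulate_unaided <- function(x, ag, spec = filterbank_spec(x$rate)) {
  x <- to_stereo(x)
  out <- vapply(c("left", "right"), function(ear) {
    ch <- if (ear == "left") 1L else 2L
    g <- hl_band_gains(ag, ear, x$rate)
    apply_band_gains(mono_channel(x, ch), g, spec)$samples[, 1]
  }, numeric(n_samples(x)))
  audio_buffer(out, x$rate)
}

# Band gains implementing the threshold-elevation attenuation for one ear:
# audiogram thresholds interpolated onto the ear's own audiometric
# frequencies, negated. Centers above Nyquist are dropped (their flat
# extrapolation is carried by the bin interpolation).
hl_band_gains <- function(ag, ear, rate) {
  e <- ag[[ear]]
  keep <- e$freq <= rate / 2
  band_gains(e$freq[keep], -e$threshold[keep])
}
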