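#' Multi-channel compressor parameters
#'
#' Wide dynamic range compression (WDRC) configuration for one ear:
#' contiguous frequency channels, each with a lower kneepoint (compression
#' threshold, dB SPL input), compression ratio, gain at a 65 dB SPL input,
#' and an output limiting ceiling; attack and release time constants are
#' global.
#'
#' @param edges Channel edge frequencies (Hz), ascending, spanning 0 to
#'   Nyquist; length = channels + 1.
#' @param g65 Gain at 65 dB SPL input per channel (dB).
#' @param cr Compression ratio per channel (>= 1).
#' @param knee Lower kneepoint per channel (dB SPL), in \[20, 60\].
#' @param ceiling Output limiting ceiling (dB SPL), >= kneepoint.
#' @param attack_ms,release_ms Envelope time constants (ms); attack must be
#'   shorter than release.
#' @export
compressor_params <- function(edges, g65, cr, knee = 40, ceiling = 105,
                              attack_ms = 5, release_ms = 100) {
  n_ch <- length(edges) - 1L
  if (n_ch < 1L) stop("at least one channel required", call. = FALSE)
  if (any(diff(edges) <= 0)) stop("edges must be strictly ascending", call. = FALSE)
  g65 <- rep_len(g65, n_ch); cr <- rep_len(cr, n_ch)
  knee <- rep_len(knee, n_ch); ceiling <- rep_len(ceiling, n_ch)
  if (any(cr < 1)) stop("compression ratios must be >= 1", call. = FALSE)
  if (any(knee < 20 | knee > 60))
    stop("kneepoints must lie in [20, 60] dB SPL", call. = FALSE)
  if (any(ceiling < knee)) stop("ceiling must be >= kneepoint", call. = FALSE)
  if (attack_ms >= release_ms) stop("attack must be shorter than release", call. = FALSE)
  structure(list(edges = as.numeric(edges), g65 = g65, cr = cr, knee = knee,
                 ceiling = ceiling, attack_ms = attack_ms,
                 release_ms = release_ms),
            class = "compressor_params")
}

#' @export
print.compressor_params <- function(x, ...) {
  n_ch <- length(x$g65)
  cat(sprintf("<compressor_params> %d channel(s), attack %g ms, release %g ms\n",
              n_ch, x$attack_ms, x$release_ms))
  print(data.frame(lo_hz = x$edges[-(n_ch + 1)], hi_hz = x$edges[-1],
                   g65_db = x$g65, cr = x$cr, knee_spl = x$knee,
                   ceiling_spl = x$ceiling), row.names = FALSE)
  invisible(x)
}

# Channel edges: 6 channels, octave-spaced from 250 Hz up to Nyquist --
# typical commercial WDRC banding.
wdrc_edges <- function(rate) c(0, 250, 500, 1000, 2000, 4000, rate / 2)

# Prescription center of each channel: geometric mean of its edges (the
# lowest channel uses half its upper edge as the effective lower bound).
channel_centers <- function(edges) {
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  lo[1] <- hi[1] / 2
  pmin(sqrt(lo * hi), 16000)
}

# Registered prescription rules: audiogram -> per-channel (g65, cr).
# "dsl_like_halfgain" is a DSL-style level-dependent rule kept deliberately
# simple and self-contained: half-gain at conversational level with a
# loss-dependent compression ratio. A faithful DSL v5.0 table can be
# registered in its place.
.prescription_rules <- list(
  dsl_like_halfgain = function(hl) {
    list(g65 = clamp(0.5 * hl, 0, 50),
         cr = clamp(1 + hl / 100, 1, 3))
  }
)

#' Prescribe compression from an audiogram
#'
#' Maps one ear's interpolated hearing levels onto per-channel WDRC
#' parameters through a named prescription rule. The default
#' `"dsl_like_halfgain"` rule gives `G65 = clamp(HL/2, 0, 50)` dB and
#' `CR = clamp(1 + HL/100, 1, 3)` with a 40 dB SPL kneepoint and a
#' 105 dB SPL ceiling; a 0 dB HL ear prescribes a transparent compressor
#' (G65 = 0, CR = 1).
#'
#' @param ag An `audiogram`.
#' @param ear `"left"` or `"right"`.
#' @param rule Prescription rule name (see `names(hearsim:::.prescription_rules)`).
#' @param rate Sample rate (Hz) used to place the top channel edge at
#'   Nyquist.
#' @return A `compressor_params`.
#' @export
prescribe <- function(ag, ear = c("left", "right"), rule = "dsl_like_halfgain",
                      rate = 44100) {
  ear <- match.arg(ear)
  if (!rule %in% names(.prescription_rules))
    stop("unknown prescription rule '", rule, "'; available: ",
         paste(names(.prescription_rules), collapse = ", "), call. = FALSE)
  edges <- wdrc_edges(rate)
  hl <- interpolate_to_bands(ag, ear, channel_centers(edges))
  p <- .prescription_rules[[rule]](hl)
  compressor_params(edges, g65 = p$g65, cr = p$cr)
}

#' Static input/output curve of one compressor channel
#'
#' Below the kneepoint the channel is linear (slope 1); above it the slope
#' is 1/CR. The curve is continuous at the kneepoint and anchored to pass
#' through (65, 65 + G65); output is hard-limited at the ceiling.
#'
#' @param p A `compressor_params`.
#' @param channel Channel index.
#' @param level_in Input level(s), dB SPL (vectorized).
#' @return Output level(s), dB SPL.
#' @export
static_io_curve <- function(p, channel, level_in) {
  g65 <- p$g65[channel]; cr <- p$cr[channel]
  knee <- p$knee[channel]; ceil <- p$ceiling[channel]
  out_knee <- (65 + g65) - (65 - knee) / cr
  out <- ifelse(level_in < knee,
                out_knee + (level_in - knee),
                out_knee + (level_in - knee) / cr)
  pmin(out, ceil)
}

env_alpha <- function(tau_ms, rate) exp(-1 / (rate * tau_ms / 1000))

#' Apply multi-channel wide dynamic range compression
#'
#' The signal is split into the compressor's channels by exact zero-phase
#' frequency-domain filtering (complementary raised-cosine band masks, so
#' the channels sum back to the input to machine precision). Per channel,
#' the instantaneous band power is first
#' averaged by a symmetric one-pole smoother at the attack time constant (an
#' unbiased RMS detector for steady tones), then an attack/release one-pole
#' envelope follower tracks it; the envelope is converted to dB SPL through
#' the calibration map and drives a time-varying gain so that steady-state
#' levels follow `static_io_curve()`. Channels are summed; the output has
#' the same length as the input.
#'
#' @param x A mono `audio_buffer`.
#' @param p A `compressor_params`; its top edge must be at `x`'s Nyquist.
#' @param calib A `calibration_map`.
#' @return A mono `audio_buffer`.
#' @export
compress <- function(x, p, calib) {
  if (n_channels(x) != 1L) stop("x must be mono", call. = FALSE)
  a_att <- env_alpha(p$attack_ms, x$rate)
  a_rel <- env_alpha(p$release_ms, x$rate)
  base <- spl_offset_db(calib)
  chans <- band_split(x, p$edges)
  out <- numeric(n_samples(x))
  for (ci in seq_along(chans)) {
    s <- chans[[ci]]$samples[, 1]
    p_pre <- as.numeric(stats::filter((1 - a_att) * s^2, a_att,
                                      method = "recursive"))
    env <- env_follow(p_pre, a_att, a_rel, 0)
    lev <- base + 10 * log10(pmax(env, 1e-20))
    gain_db <- static_io_curve(p, ci, lev) - lev
    out <- out + s * db_to_lin(gain_db)
  }
  audio_buffer(out, x$rate)
}

#' Simulate the aided hearing profile
#'
#' Per ear: the input is amplified by the prescribed WDRC compressor and
#' then passed through that ear's hearing-loss attenuation filter -- aided
#' sound is heard through the impaired ear. Mono input is duplicated onto
#' both ear paths; output is stereo. With a flat 0 dB HL audiogram both
#' stages are transparent and the chain is an identity.
#'
#' @param x An `audio_buffer` (mono or stereo).
#' @param ag An `audiogram`.
#' @param calib A `calibration_map`.
#' @param rule Prescription rule name.
#' @param spec Optional `filterbank_spec`.
#' @return A stereo `audio_buffer`.
#' @export
simulate_aided <- function(x, ag, calib = default_calibration(),
                           rule = "dsl_like_halfgain",
                           spec = filterbank_spec(x$rate)) {
  x <- to_stereo(x)
  out <- vapply(c("left", "right"), function(ear) {
    ch <- if (ear == "left") 1L else 2L
    p <- prescribe(ag, ear, rule = rule, rate = x$rate)
    aided <- compress(mono_channel(x, ch), p, calib)
    apply_band_gains(aided, hl_band_gains(ag, ear, x$rate), spec)$samples[, 1]
  }, numeric(n_samples(x)))
  audio_buffer(out, x$rate)
}
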