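# Shared test helpers: small deterministic signals and oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Absolute-tolerance comparison (expect_equal's tolerance is relative, which
# is meaningless for dB-scale quantities).
expect_within <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}

# Steady-state segment of a processed tone: interior window clear of the
# onset/offset edge ringing an abruptly gated tone spreads into all bands.
steady_segment <- function(x, from = 0.5, to = 0.9) {
  n <- n_samples(x)
  audio_buffer(x$samples[round(n * from):round(n * to), , drop = FALSE],
               x$rate)
}

test_calib <- default_calibration()

# A short sine buffer at a given frequency/rate, unit amplitude.
sine_buffer <- function(freq, duration = 1, rate = 16000, amp = 1) {
  t <- (seq_len(round(duration * rate)) - 1) / rate
  audio_buffer(amp * sin(2 * pi * freq * t), rate)
}

# Random audiogram with realistic sloping structure: a base loss at 250 Hz
# plus non-negative octave steps, capped at 90 dB HL.
random_audiogram <- function() {
  freqs <- c(250, 500, 1000, 2000, 4000, 8000)
  thr <- pmin(cumsum(c(runif(1, 0, 40), runif(5, 0, 20))), 90)
  v <- stats::setNames(thr, freqs)
  audiogram(v, v)
}

# Third-octave band levels (dB SPL) of a mono/stereo buffer.
band_levels <- function(x, calib = test_calib) {
  hearsim:::band_levels_spl(x, calib)
}

nominal_bands <- hearsim:::third_octave_nominal()
exact_centers <- hearsim:::third_octave_centers()

# Sample-by-sample scalar compressor oracle: same detector law as the
# published model (symmetric power pre-average at the attack constant, then
# attack/release one-pole), single channel, plain R loop.
oracle_compress <- function(s, rate, p, calib) {
  a_att <- exp(-1 / (rate * p$attack_ms / 1000))
  a_rel <- exp(-1 / (rate * p$release_ms / 1000))
  base <- hearsim:::spl_offset_db(calib)
  pre <- 0; env <- 0
  out <- numeric(length(s))
  for (n in seq_along(s)) {
    pre <- a_att * pre + (1 - a_att) * s[n]^2
    a <- if (pre > env) a_att else a_rel
    env <- a * env + (1 - a) * pre
    lev <- base + 10 * log10(max(env, 1e-20))
    g <- static_io_curve(p, 1, lev) - lev
    out[n] <- s[n] * 10^(g / 20)
  }
  out
}

# Short-time RMS level trace (dB SPL) on non-overlapping frames.
level_trace <- function(s, rate, calib = test_calib, frame_s = 0.005) {
  flen <- round(rate * frame_s)
  n <- (length(s) %/% flen) * flen
  m <- matrix(s[seq_len(n)], nrow = flen)
  hearsim:::spl_offset_db(calib) + 10 * log10(pmax(colMeans(m^2), 1e-30))
}
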