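test_that("the half-gain prescription maps thresholds to channel gains", {
  flat0 <- audiogram_preset("normal")
  p0 <- prescribe(flat0, "left", rate = 32000)
  expect_true(all(p0$g65 == 0) && all(p0$cr == 1))

  freqs <- c(250, 500, 1000, 2000, 4000, 8000)
  flat60 <- audiogram(stats::setNames(rep(60, 6), freqs))
  p60 <- prescribe(flat60, "left", rate = 32000)
  expect_equal(p60$g65, rep(30, 6))
  expect_equal(p60$cr, rep(1.6, 6))
  expect_true(all(p60$knee == 40) && all(p60$ceiling == 105))

  slope <- prescribe(audiogram_preset("sloping_snhl"), "left", rate = 32000)
  expect_true(all(diff(slope$g65) >= 0))

  expect_error(prescribe(flat0, "left", rule = "nal_nl2"),
               "unknown prescription rule")
})

test_that("the static I/O curve is anchored, kinked at the knee and limited", {
  p_lin <- compressor_params(c(0, 8000), g65 = 12, cr = 1)
  for (L in c(30, 55, 80))
    expect_equal(static_io_curve(p_lin, 1, L), L + 12)

  p2 <- compressor_params(c(0, 8000), g65 = 8, cr = 2, knee = 40)
  expect_equal(static_io_curve(p2, 1, 65), 65 + 8)
  expect_equal(static_io_curve(p2, 1, 85), static_io_curve(p2, 1, 65) + 10)

  withr::local_seed(13)
  for (i in 1:10) {
    p <- compressor_params(c(0, 8000), g65 = runif(1, 0, 40),
                           cr = runif(1, 1, 3), knee = runif(1, 20, 60),
                           ceiling = 120)
    L <- seq(0, 110, by = 0.25)
    out <- static_io_curve(p, 1, L)
    expect_true(all(diff(out) >= -1e-9))              # non-decreasing
    open <- L > p$knee[1] + 1 & out < 120 - 1         # above knee, below limit
    expect_lt(max(abs(diff(out[open]) / 0.25 - 1 / p$cr[1])),
              1e-6)                                   # slope above knee
    k <- p$knee[1]
    expect_equal(static_io_curve(p, 1, k - 1e-6), static_io_curve(p, 1, k),
                 tolerance = 1e-4)                    # continuity
  }
})

test_that("transparent compression is an identity", {
  x <- generate_fixture("speech_shaped", 0.5, 16000, seed = 21)
  p <- compressor_params(c(0, 250, 500, 1000, 2000, 4000, 8000),
                         g65 = 0, cr = 1)
  y <- compress(x, p, test_calib)
  expect_lt(max(abs(y$samples - x$samples)), 1e-4)
})

test_that("steady-state compression follows the static curve at the anchor", {
  fs <- 44100
  tone <- set_spl(sine_buffer(1000, 1, fs), 65, test_calib)
  p <- compressor_params(c(0, fs / 2), g65 = 20, cr = 2)
  y <- compress(tone, p, test_calib)
  expect_within(measure_spl(steady_segment(y), test_calib), 85, 0.5)
})

test_that("a level step settles onto the static curve like the scalar oracle", {
  fs <- 16000
  calib <- test_calib
  p <- compressor_params(c(0, fs / 2), g65 = 15, cr = 2)
  t <- (0:(fs - 1)) / fs
  amp50 <- 10^((50 - hearsim:::spl_offset_db(calib)) / 20) * sqrt(2)
  amp80 <- 10^((80 - hearsim:::spl_offset_db(calib)) / 20) * sqrt(2)
  s <- sin(2 * pi * 1000 * t) * c(rep(amp50, fs / 2), rep(amp80, fs / 2))
  y <- compress(audio_buffer(s, fs), p, calib)$samples[, 1]
  y_or <- oracle_compress(s, fs, p, calib)

  lv <- level_trace(y, fs)
  lv_or <- level_trace(y_or, fs)
  expect_lt(max(abs(lv - lv_or)), 0.5)

  # settles to the static-curve value within 3x the release time of the step
  settle <- round((0.5 + 3 * p$release_ms / 1000) * fs)
  tail_spl <- measure_spl(audio_buffer(y[(settle + 1):fs], fs), calib)
  expect_within(tail_spl, static_io_curve(p, 1, 80), 0.5)
})

test_that("steady-state levels match the static curve across channels and levels", {
  fs <- 32000
  p <- prescribe(audiogram_preset("sloping_snhl"), "left", rate = fs)
  centers <- hearsim:::channel_centers(p$edges)
  for (ci in c(1, 4, 6)) {
    for (L in c(45, 70, 95)) {
      x <- set_spl(sine_buffer(centers[ci], 0.6, fs), L, test_calib)
      y <- compress(x, p, test_calib)
      expect_within(measure_spl(steady_segment(y), test_calib),
                    static_io_curve(p, ci, L), 0.5)
    }
  }
})

test_that("the aided chain is transparent for normal hearing", {
  x <- generate_fixture("speech_shaped", 0.5, 16000, seed = 22)
  y <- simulate_aided(x, audiogram_preset("normal"), test_calib)
  expect_lt(max(abs(y$samples[, 1] - x$samples[, 1])), 1e-4)
  expect_lt(max(abs(y$samples[, 2] - x$samples[, 1])), 1e-4)
})

test_that("aids improve audibility but do not restore normal hearing", {
  x <- set_spl(generate_fixture("speech_shaped", 1, 32000, seed = 23),
               65, test_calib)
  ag <- audiogram_preset("sloping_snhl")
  unaided <- simulate_unaided(x, ag)
  aided <- simulate_aided(x, ag, test_calib)
  expect_lt(buffer_rms(unaided), buffer_rms(aided))
  expect_lt(buffer_rms(aided), buffer_rms(x))
})

test_that("the aided path is deterministic", {
  x <- generate_fixture("speech_shaped", 0.3, 16000, seed = 24)
  ag <- audiogram_preset("sloping_snhl")
  expect_identical(simulate_aided(x, ag, test_calib)$samples,
                   simulate_aided(x, ag, test_calib)$samples)
})
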