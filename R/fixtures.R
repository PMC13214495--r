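#' Synthetic audio fixtures
#'
#' Seed-reproducible stand-ins for recorded stimuli, defined by formula so
#' every analysis is self-contained:
#'
#' * `"speech_shaped"`: Gaussian noise spectrally shaped flat over
#'   100--500 Hz with a -9 dB/octave rolloff above 500 Hz (and a steep
#'   low-cut below 100 Hz), amplitude-modulated at 4 Hz with depth 0.6 as a
#'   syllabic-envelope stand-in.
#' * `"babble"`: the sum of 8 independently generated speech-shaped streams.
#' * `"tone:<freqHz>"`: a pure sine at the given frequency.
#' * `"music_tones"`: an arpeggiated harmonic tone sequence spanning
#'   262--3520 Hz (instrumental-music stand-in).
#' * `"white"`: Gaussian white noise.
#'
#' All fixtures are scaled to the stated RMS. The caller's RNG state is
#' left untouched; the same `(name, duration, rate, seed)` always yields a
#' bit-identical buffer.
#'
#' @param name Fixture identifier (see above).
#' @param duration Duration in seconds.
#' @param rate Sample rate in Hz.
#' @param seed Integer seed.
#' @param rms Target RMS amplitude, full scale (default 0.1, i.e. -20 dBFS
#'   -- the conversational anchor of the default calibration).
#' @return A mono `audio_buffer`.
#' @export
generate_fixture <- function(name, duration = 6, rate = 44100, seed = 1L,
                             rms = 0.1) {
  n <- max(1L, round(duration * rate))
  samples <- with_local_seed(seed, {
    if (name == "white") {
      stats::rnorm(n)
    } else if (name == "speech_shaped") {
      gen_speech_shaped(n, rate)
    } else if (name == "babble") {
      rowSums(vapply(1:8, function(i) gen_speech_shaped(n, rate),
                     numeric(n)))
    } else if (grepl("^tone:", name)) {
      f <- suppressWarnings(as.numeric(sub("^tone:", "", name)))
      if (!is.finite(f) || f <= 0 || f >= rate / 2)
        stop("tone frequency must lie in (0, Nyquist)", call. = FALSE)
      sin(2 * pi * f * (seq_len(n) - 1) / rate)
    } else if (name == "music_tones") {
      gen_music_tones(n, rate)
    } else {
      stop("unknown fixture '", name, "'; available: ",
           "speech_shaped, babble, tone:<freqHz>, music_tones, white",
           call. = FALSE)
    }
  })
  scale_to_rms(audio_buffer(samples, rate), rms)
}

#' @rdname generate_fixture
#' @export
list_fixtures <- function() {
  c("speech_shaped", "babble", "tone:<freqHz>", "music_tones", "white")
}

# Speech-shaped modulated noise: white Gaussian noise shaped in the
# frequency domain (flat 100-500 Hz, -9 dB/oct above 500 Hz, +24 dB/oct
# low-cut below 100 Hz), then 4 Hz sinusoidal amplitude modulation at
# depth 0.6 with a random phase (so summed streams desynchronize, as in
# babble). Consumes the ambient RNG stream (seeding is the caller's job).
gen_speech_shaped <- function(n, rate) {
  phi <- stats::runif(1, 0, 2 * pi)
  w <- stats::rnorm(n)
  n_half <- n %/% 2L + 1L
  f <- (seq_len(n_half) - 1L) * rate / n
  h <- numeric(n_half)
  h[f >= 100 & f <= 500] <- 1
  hi <- f > 500
  h[hi] <- (f[hi] / 500)^(-1.5)          # -9.03 dB/octave
  lo <- f < 100 & f > 0
  h[lo] <- (f[lo] / 100)^4               # +24 dB/octave low-cut
  h_full <- numeric(n)
  h_full[seq_len(n_half)] <- h
  if (n > 2L) h_full[(n_half + 1L):n] <- h[if (n %% 2L == 0L) (n_half - 1L):2L
                                           else n_half:2L]
  shaped <- Re(stats::fft(stats::fft(w) * h_full, inverse = TRUE)) / n
  t <- (seq_len(n) - 1) / rate
  shaped * (1 + 0.6 * sin(2 * pi * 4 * t + phi))
}

# Arpeggiated harmonic tones: an ascending/descending major-arpeggio note
# cycle from C4 (262 Hz) to A7 (3520 Hz), 200 ms notes with three harmonics
# (amplitudes 1, 1/2, 1/4) and 10 ms raised-cosine ramps. Deterministic.
gen_music_tones <- function(n, rate) {
  notes <- c(262, 330, 392, 523, 659, 784, 1047, 1319, 1568, 2093, 2637, 3520)
  notes <- c(notes, rev(notes)[-1])
  note_len <- round(0.2 * rate)
  ramp_len <- round(0.01 * rate)
  ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_len) / ramp_len))
  envlp <- c(ramp, rep(1, max(0, note_len - 2 * ramp_len)), rev(ramp))
  out <- numeric(n)
  pos <- 0L; k <- 0L
  while (pos < n) {
    f0 <- notes[(k %% length(notes)) + 1L]
    len <- min(note_len, n - pos)
    t <- (seq_len(len) - 1) / rate
    tone <- numeric(len)
    for (h in 1:3) {
      if (h * f0 < rate / 2)
        tone <- tone + (0.5^(h - 1)) * sin(2 * pi * h * f0 * t)
    }
    out[(pos + 1L):(pos + len)] <- tone * envlp[seq_len(len)]
    pos <- pos + len; k <- k + 1L
  }
  out
}

#' The packaged conversational-speech fixture
#'
#' The speech-shaped fixture at its calibration anchor: RMS 0.1 full scale,
#' which the default calibration maps to 63.5 dB SPL at volume 20 -- the
#' center of the 62--65 dB SPL conversational window.
#' @param duration Duration (s); at least 5 s for LTASS work.
#' @param rate Sample rate (Hz).
#' @param seed Integer seed.
#' @export
conversational_fixture <- function(duration = 6, rate = 44100, seed = 20L) {
  generate_fixture("speech_shaped", duration, rate, seed, rms = 0.1)
}
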