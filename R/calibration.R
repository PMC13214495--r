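#' Calibration map: digital level to dB SPL
#'
#' An affine mapping between digital RMS (dBFS) and acoustic level (dB SPL):
#' `level(x) = offset + 20*log10(RMS(x)) - attenuation(volume)`, where
#' `offset` is the dB SPL produced by a full-scale (0 dBFS RMS) signal at
#' the reference volume, and the volume control attenuates linearly in dB
#' per step below the reference setting.
#'
#' @param offset dB SPL of a full-scale RMS signal at reference volume;
#'   must lie in \[70, 140\].
#' @param volume Volume setting, 0--100.
#' @param db_per_step Attenuation per volume step below `ref_volume` (dB,
#'   non-negative).
#' @param ref_volume Volume setting at which attenuation is zero.
#' @export
calibration_map <- function(offset, volume = 20, db_per_step = 0.5,
                            ref_volume = 100) {
  if (!is.finite(offset) || offset < 70 || offset > 140)
    stop("offset must lie in [70, 140] dB SPL", call. = FALSE)
  if (db_per_step < 0) stop("db_per_step must be non-negative", call. = FALSE)
  if (volume < 0 || volume > 100) stop("volume must lie in [0, 100]", call. = FALSE)
  structure(list(offset = offset, volume = volume, db_per_step = db_per_step,
                 ref_volume = ref_volume),
            class = "calibration_map")
}

# Effective dB SPL corresponding to 0 dBFS RMS at the map's volume setting.
spl_offset_db <- function(calib) {
  calib$offset - calib$db_per_step * max(0, calib$ref_volume - calib$volume)
}

#' Default calibration
#'
#' The offset is chosen so the packaged conversational speech-shaped fixture
#' (RMS 0.1 full scale, i.e. -20 dBFS) at the default volume setting of 20
#' measures 63.5 dB SPL -- the center of the 62--65 dB SPL conversational
#' window the simulator is anchored to. Hardware transfer functions are out
#' of scope, so this anchor is definitional.
#' @param volume Volume setting (default 20).
#' @export
default_calibration <- function(volume = 20) {
  # 63.5 = offset + 20*log10(0.1) - 0.5*(100 - 20)  =>  offset = 123.5
  calibration_map(offset = 123.5, volume = volume, db_per_step = 0.5,
                  ref_volume = 100)
}

#' Measure broadband level in dB SPL
#'
#' Scale-covariant by construction: scaling samples by `a > 0` adds exactly
#' `20*log10(a)` dB.
#' @param x An `audio_buffer`.
#' @param calib A `calibration_map`.
#' @export
measure_spl <- function(x, calib) {
  r <- buffer_rms(x)
  if (r <= 0) stop("cannot measure a silent buffer", call. = FALSE)
  spl_offset_db(calib) + lin_to_db(r)
}

#' Scale a buffer to a target broadband level
#' @param x An `audio_buffer`.
#' @param spl Target level in dB SPL.
#' @param calib A `calibration_map`.
#' @export
set_spl <- function(x, spl, calib) {
  cur <- measure_spl(x, calib)
  audio_buffer(x$samples * db_to_lin(spl - cur), x$rate)
}

## ---- third-octave analysis ------------------------------------------------

# Exact base-2 third-octave center frequencies 125 Hz -- 8 kHz (the ANSI
# nominal series rounds these for display).
third_octave_centers <- function() 1000 * 2^((-9:9) / 3)

third_octave_nominal <- function() {
  c(125, 160, 200, 250, 315, 400, 500, 630, 800, 1000,
    1250, 1600, 2000, 2500, 3150, 4000, 5000, 6300, 8000)
}

# Band powers (linear, mean-square units) per frame from a mono signal:
# Hann-windowed periodogram frames integrated into third-octave bands.
# Returns list(frame_power = frames x bands matrix, centers, nominal).
frame_band_powers <- function(samples, rate, frame_s = 0.125, overlap = 0.5) {
  centers <- third_octave_centers()
  lo <- centers * 2^(-1 / 6)
  hi <- centers * 2^(1 / 6)
  flen <- round(rate * frame_s)
  hop <- max(1L, round(flen * (1 - overlap)))
  n <- length(samples)
  if (n < flen) stop("signal shorter than one analysis frame", call. = FALSE)
  starts <- seq(1L, n - flen + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(flen) - 1) / flen))
  wss <- sum(w^2)
  n_half <- flen %/% 2L + 1L
  f <- (seq_len(n_half) - 1L) * rate / flen
  # one-sided power scaling: double interior bins so bins sum to mean-square
  one_sided <- c(1, rep(2, n_half - 2L), if (flen %% 2L == 0L) 1 else 2)
  band_of <- findInterval(f, c(lo, hi[length(hi)]))  # 0 = below, len+1 = above
  frames <- vapply(starts, function(s) {
    X <- stats::fft(samples[s:(s + flen - 1L)] * w)[seq_len(n_half)]
    p_bin <- (Mod(X)^2 / (flen * wss)) * one_sided
    vapply(seq_along(centers), function(b) sum(p_bin[band_of == b]),
           numeric(1))
  }, numeric(length(centers)))
  list(frame_power = t(frames), centers = centers,
       nominal = third_octave_nominal())
}

# Long-term third-octave band levels in dB SPL for a buffer (channels are
# averaged to mono first).
band_levels_spl <- function(x, calib, frame_s = 0.125) {
  fb <- frame_band_powers(to_mono(x)$samples[, 1], x$rate, frame_s = frame_s)
  lt <- colMeans(fb$frame_power)
  spl_offset_db(calib) + 10 * log10(pmax(lt, 1e-30))
}

#' Compute an LTASS report with dynamic speech range
#'
#' Long-term average speech spectrum: Hann-windowed 125 ms frames at 50%
#' overlap are integrated into third-octave bands (125 Hz--8 kHz); the
#' long-term level per band is the dB of the mean band power, and the
#' dynamic speech range is the 30th/99th percentile of the short-term
#' (per-frame) band levels, all converted to dB SPL through the calibration
#' map. Stereo input is averaged to mono.
#'
#' @param x An `audio_buffer`, at least 5 s long.
#' @param calib A `calibration_map`.
#' @return An object of class `ltass_report`: a list with `bands` (a tibble
#'   with columns `band` (nominal Hz), `center` (exact Hz), `ltass_db`,
#'   `p30_db`, `p99_db`) and `broadband_spl`.
#' @export
compute_ltass <- function(x, calib) {
  if (n_samples(x) / x$rate < 5)
    stop("compute_ltass needs at least 5 s of material", call. = FALSE)
  fb <- frame_band_powers(to_mono(x)$samples[, 1], x$rate)
  base <- spl_offset_db(calib)
  frame_db <- base + 10 * log10(pmax(fb$frame_power, 1e-30))
  bands <- tibble::tibble(
    band = fb$nominal,
    center = fb$centers,
    ltass_db = base + 10 * log10(pmax(colMeans(fb$frame_power), 1e-30)),
    p30_db = apply(frame_db, 2, stats::quantile, probs = 0.30, names = FALSE),
    p99_db = apply(frame_db, 2, stats::quantile, probs = 0.99, names = FALSE))
  structure(list(bands = bands, broadband_spl = measure_spl(x, calib)),
            class = "ltass_report")
}

#' @export
print.ltass_report <- function(x, ...) {
  cat(sprintf("<ltass_report> broadband %.1f dB SPL\n", x$broadband_spl))
  print(x$bands, n = nrow(x$bands))
  invisible(x)
}

#' Plot an LTASS report
#'
#' Speechmap-style display: long-term average spectrum with the shaded
#' p30--p99 dynamic speech range per third-octave band.
#' @param object An `ltass_report`.
#' @param ... Unused.
#' @export
autoplot.ltass_report <- function(object, ...) {
  b <- object$bands
  ggplot2::ggplot(b, ggplot2::aes(x = .data$center)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p30_db, ymax = .data$p99_db),
                         fill = "darkgreen", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ltass_db), colour = "darkgreen") +
    ggplot2::geom_point(ggplot2::aes(y = .data$ltass_db), colour = "darkgreen") +
    ggplot2::scale_x_log10(breaks = c(125, 250, 500, 1000, 2000, 4000, 8000)) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Band level (dB SPL)",
                  title = "LTASS with dynamic speech range (p30–p99)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

## ---- Speechmap-style chain verification -----------------------------------

#' Verify a render chain against audibility expectations
#'
#' Renders the chain for a given mode, measures SPL and LTASS at input and
#' output, and checks Speechmap-style expectations: conversational input
#' level within \[62, 65\] dB SPL; for unaided mode, per-band attenuation
#' equal to the interpolated hearing level within a mid-band tolerance; for
#' normal mode, an identity spectrum; for aided mode, band levels at least
#' the unaided levels wherever there is loss. Failures are carried in the
#' report, not raised.
#'
#' @param source An `audio_buffer` (mono), e.g. the conversational fixture
#'   at its calibrated level; needs >= 5 s for LTASS.
#' @param ag An `audiogram`.
#' @param mode `"normal"`, `"unaided"` or `"aided"`.
#' @param sc A `scenario` (default quiet).
#' @param calib A `calibration_map`.
#' @param ear Ear to verify (`"left"` or `"right"`).
#' @param band_tol_db Per-band tolerance for the unaided attenuation check
#'   over the mid-bands 250 Hz--8 kHz (dB).
#' @return A list of class `verification_report` with `checks` (tibble:
#'   check, value, expected, pass), `input_ltass`, `output_ltass`.
#' @export
verify_chain <- function(source, ag, mode = c("normal", "unaided", "aided"),
                         sc = scenario("quiet"), calib = default_calibration(),
                         ear = c("left", "right"), band_tol_db = 2) {
  mode <- match.arg(mode)
  ear <- match.arg(ear)
  ch <- if (ear == "left") 1L else 2L
  staged <- apply_environment(source, sc)
  out <- render_mode(staged, mode, ag, calib)
  in_rep <- compute_ltass(staged, calib)
  out_ear <- mono_channel(out, ch)
  out_rep <- compute_ltass(out_ear, calib)
  in_spl <- measure_spl(staged, calib)

  checks <- list(tibble::tibble(
    check = "input level conversational (62-65 dB SPL)",
    value = in_spl, expected = "[62, 65]",
    pass = in_spl >= 62 && in_spl <= 65))

  mid <- in_rep$bands$band >= 250 & in_rep$bands$band <= 8000
  if (mode == "normal") {
    d <- abs(out_rep$bands$ltass_db - in_rep$bands$ltass_db)
    checks <- c(checks, list(tibble::tibble(
      check = "normal chain identity (max band deviation, dB)",
      value = max(d[mid]), expected = "<= 0.5",
      pass = max(d[mid]) <= 0.5)))
  } else if (mode == "unaided") {
    hl <- interpolate_to_bands(ag, ear, in_rep$bands$center)
    att <- in_rep$bands$ltass_db - out_rep$bands$ltass_db
    err <- abs(att - hl)
    checks <- c(checks, list(tibble::tibble(
      check = "per-band attenuation matches hearing level (max error, dB)",
      value = max(err[mid]), expected = paste0("<= ", band_tol_db),
      pass = max(err[mid]) <= band_tol_db)))
  } else {
    unaided <- compute_ltass(
      mono_channel(render_mode(staged, "unaided", ag, calib), ch), calib)
    hl <- interpolate_to_bands(ag, ear, in_rep$bands$center)
    loss <- mid & hl > 0
    gain_over_unaided <-
      out_rep$bands$ltass_db[loss] - unaided$bands$ltass_db[loss]
    checks <- c(checks, list(tibble::tibble(
      check = "aided band levels >= unaided where HL > 0 (min delta, dB)",
      value = min(gain_over_unaided), expected = ">= 0",
      pass = min(gain_over_unaided) >= 0)))
  }
  structure(list(checks = do.call(rbind, checks),
                 mode = mode, ear = ear,
                 input_ltass = in_rep, output_ltass = out_rep),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> mode=%s ear=%s  %s\n", x$mode, x$ear,
              if (all(x$checks$pass)) "PASS" else "FAIL"))
  print(x$checks)
  invisible(x)
}

#' Write a verification report to CSV/JSON
#' @param report A `verification_report`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_verification <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    b <- report$output_ltass$bands
    utils::write.csv(
      data.frame(band_hz = b$band, ltass_db = b$ltass_db,
                 p30_db = b$p30_db, p99_db = b$p99_db),
      csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(mode = report$mode, ear = report$ear,
           pass = all(report$checks$pass),
           checks = report$checks,
           broadband_spl = report$output_ltass$broadband_spl),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
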