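#' Listening-environment scenarios
#'
#' A scenario describes one of the four demonstration environments: speech
#' in quiet, speech in noise at an adjustable SNR, speech at a talker
#' distance (inverse square law), and music. The environment kind determines
#' which fields are required: `snr_db` for noise, `distance` for distance.
#' A noise scenario may also carry a distance, in which case the SNR is
#' defined at the reference distance and only the speech is
#' distance-attenuated (ambient noise model), so the effective SNR degrades
#' with distance.
#'
#' @param kind `"quiet"`, `"noise"`, `"distance"` or `"music"`.
#' @param snr_db Signal-to-noise ratio in dB (noise scenarios).
#' @param distance Talker distance (> 0), in `distance_unit`.
#' @param distance_unit `"m"` or `"ft"` (1 ft = 0.3048 m exactly).
#' @param ref_distance_m Reference distance in meters (default 1 m, the
#'   free-field speech reference).
#' @param noise Noise source: `"fixture:<name>"` (e.g. `"fixture:babble"`)
#'   or a WAV file path.
#' @param noise_seed Seed for fixture-generated noise.
#' @export
scenario <- function(kind = c("quiet", "noise", "distance", "music"),
                     snr_db = NULL, distance = NULL,
                     distance_unit = c("m", "ft"), ref_distance_m = 1,
                     noise = "fixture:babble", noise_seed = 1L) {
  kind <- match.arg(kind)
  distance_unit <- match.arg(distance_unit)
  if (kind == "noise") {
    if (is.null(snr_db) || !is.finite(snr_db))
      stop("noise scenario requires a finite snr_db", call. = FALSE)
  }
  if (kind == "distance") {
    if (is.null(distance))
      stop("distance scenario requires a distance", call. = FALSE)
  }
  if (!is.null(distance) && distance <= 0)
    stop("distance must be positive", call. = FALSE)
  if (ref_distance_m <= 0) stop("ref_distance_m must be positive", call. = FALSE)
  structure(list(kind = kind, snr_db = snr_db, distance = distance,
                 distance_unit = distance_unit, ref_distance_m = ref_distance_m,
                 noise = noise, noise_seed = as.integer(noise_seed)),
            class = "scenario")
}

feet_to_meters <- function(ft) ft * 0.3048

#' Distance attenuation by the inverse square law
#'
#' Acoustic intensity falls with the square of distance, so the level change
#' from the reference distance is `-20*log10(d / d_ref)` dB: each doubling
#' of distance costs 6.0206 dB.
#'
#' @param d Talker distance (> 0).
#' @param d_ref Reference distance (> 0), same default unit.
#' @param unit Unit of `d`: `"m"` or `"ft"`; `d_ref` is always meters.
#' @return Level change in dB (<= 0 for `d > d_ref`).
#' @export
distance_attenuation_db <- function(d, d_ref = 1, unit = c("m", "ft")) {
  unit <- match.arg(unit)
  if (!is.finite(d) || d <= 0) stop("distance must be positive", call. = FALSE)
  if (!is.finite(d_ref) || d_ref <= 0)
    stop("reference distance must be positive", call. = FALSE)
  d_m <- if (unit == "ft") feet_to_meters(d) else d
  -20 * log10(d_m / d_ref)
}

#' Mix noise into speech at a requested SNR
#'
#' The noise is scaled so that `20*log10(RMS_speech / RMS_noise)` equals the
#' requested SNR over the overlapping segment, then added; the speech
#' component is left untouched (bit-identical before summation). Noise
#' longer than the speech is trimmed, never looped.
#'
#' @param speech,noise `audio_buffer`s at the same rate; `noise` at least as
#'   long as `speech`.
#' @param snr_db Requested signal-to-noise ratio (dB, full-band RMS).
#' @return An `audio_buffer` with attributes `speech` and `scaled_noise`
#'   holding the components.
#' @export
mix_at_snr <- function(speech, noise, snr_db) {
  if (speech$rate != noise$rate)
    stop("speech and noise sample rates differ", call. = FALSE)
  if (!is.finite(snr_db)) stop("snr_db must be finite", call. = FALSE)
  if (n_samples(noise) < n_samples(speech))
    stop("noise must be at least as long as speech (noise is trimmed, not looped)",
         call. = FALSE)
  if (n_channels(noise) != n_channels(speech))
    noise <- if (n_channels(speech) == 1L) to_mono(noise) else to_stereo(noise)
  nseg <- noise$samples[seq_len(n_samples(speech)), , drop = FALSE]
  rms_n <- sqrt(mean(nseg^2))
  if (rms_n <= 0) stop("noise is silent (zero RMS)", call. = FALSE)
  scale <- (buffer_rms(speech) / rms_n) * db_to_lin(-snr_db)
  scaled <- nseg * scale
  out <- audio_buffer(speech$samples + scaled, speech$rate)
  attr(out, "speech") <- speech
  attr(out, "scaled_noise") <- audio_buffer(scaled, speech$rate)
  out
}

# Resolve a scenario's noise source to a buffer matching `speech`.
resolve_noise <- function(sc, speech) {
  src <- sc$noise
  if (startsWith(src, "fixture:")) {
    generate_fixture(sub("^fixture:", "", src),
                     duration = n_samples(speech) / speech$rate,
                     rate = speech$rate, seed = sc$noise_seed)
  } else {
    read_wav(src)
  }
}

#' Apply a listening environment to speech
#'
#' Quiet and music leave the signal unchanged. Distance scales the speech by
#' the inverse-square-law attenuation. Noise mixes the scenario's noise
#' source at the requested SNR, defined at the reference distance; if a
#' distance is also given, only the speech is then distance-attenuated
#' (the noise is ambient), so the effective SNR at the listener degrades by
#' the distance attenuation.
#'
#' @param speech An `audio_buffer`.
#' @param sc A `scenario`.
#' @param noise Optional `audio_buffer` overriding the scenario's noise
#'   source.
#' @return An `audio_buffer`; for noise scenarios, attributes `speech` and
#'   `scaled_noise` carry the components as they appear in the mix.
#' @export
apply_environment <- function(speech, sc, noise = NULL) {
  if (!inherits(sc, "scenario")) stop("sc must be a scenario", call. = FALSE)
  if (sc$kind %in% c("quiet", "music")) return(speech)
  att_db <- if (!is.null(sc$distance))
    distance_attenuation_db(sc$distance, sc$ref_distance_m, sc$distance_unit)
  else 0
  if (sc$kind == "distance") {
    return(audio_buffer(speech$samples * db_to_lin(att_db), speech$rate))
  }
  # noise: SNR set at the reference distance, then speech-only distance scaling
  if (is.null(noise)) noise <- resolve_noise(sc, speech)
  mixed <- mix_at_snr(speech, noise, sc$snr_db)
  sp <- attr(mixed, "speech")
  ns <- attr(mixed, "scaled_noise")
  sp_att <- audio_buffer(sp$samples * db_to_lin(att_db), speech$rate)
  out <- audio_buffer(sp_att$samples + ns$samples, speech$rate)
  attr(out, "speech") <- sp_att
  attr(out, "scaled_noise") <- ns
  out
}
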