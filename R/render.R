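# Profile stage shared by render() and verify_chain().
render_mode <- function(x, mode, ag, calib, rule = "dsl_like_halfgain") {
  switch(mode,
         normal = to_stereo(x),
         unaided = simulate_unaided(x, ag),
         aided = simulate_aided(x, ag, calib, rule = rule),
         stop("unknown mode '", mode, "'; expected normal, unaided or aided",
              call. = FALSE))
}

#' Describe a render job
#'
#' A render job bundles everything one end-to-end render needs: the input
#' source (a WAV path or a fixture name), the audiogram, the scenario, the
#' calibration map, the profile mode and a seed. With a fixed seed,
#' fixture-based jobs are bit-reproducible; the output sample rate always
#' equals the input rate.
#'
#' @param input A WAV file path, or `"fixture:<name>"` for a generated
#'   source.
#' @param ag An `audiogram` (object or preset name).
#' @param sc A `scenario`.
#' @param mode Profile: `"normal"`, `"unaided"` or `"aided"`.
#' @param calib A `calibration_map`.
#' @param input_spl If non-`NULL`, the source is scaled to this broadband
#'   level (dB SPL) before the environment stage; default 65 (conversational).
#' @param duration,rate Fixture duration (s) and rate (Hz) when `input` is a
#'   fixture.
#' @param seed Integer seed for fixture generation.
#' @param rule Prescription rule for aided mode.
#' @export
render_job <- function(input = "fixture:speech_shaped",
                       ag = audiogram_preset("sloping_snhl"),
                       sc = scenario("quiet"),
                       mode = c("normal", "unaided", "aided"),
                       calib = default_calibration(),
                       input_spl = 65, duration = 6, rate = 44100,
                       seed = 1L, rule = "dsl_like_halfgain") {
  mode <- match.arg(mode)
  if (is.character(ag)) ag <- audiogram_preset(ag)
  structure(list(input = input, ag = ag, sc = sc, mode = mode, calib = calib,
                 input_spl = input_spl, duration = duration, rate = rate,
                 seed = as.integer(seed), rule = rule),
            class = "render_job")
}

#' Render a job end to end
#'
#' Pipeline: load or generate the source, optionally scale it to the
#' requested input level, apply the listening environment, apply the profile
#' stage (normal passthrough / unaided loss / aided), hard-clip with a
#' logged clip count, and optionally write a float32 WAV plus a JSON sidecar
#' with the settings, measured output SPL and clip count.
#'
#' @param job A `render_job`.
#' @param out Optional output WAV path; the sidecar is written next to it as
#'   `<out>.json`.
#' @return A list of class `render_result`: `audio` (stereo
#'   `audio_buffer`), `meta` (settings + measurements), and `out` (path or
#'   `NULL`).
#' @export
render <- function(job, out = NULL) {
  src <- if (startsWith(job$input, "fixture:")) {
    generate_fixture(sub("^fixture:", "", job$input),
                     duration = job$duration, rate = job$rate, seed = job$seed)
  } else {
    to_mono(read_wav(job$input))
  }
  if (!is.null(job$input_spl)) src <- set_spl(src, job$input_spl, job$calib)
  staged <- apply_environment(src, job$sc)
  rendered <- render_mode(staged, job$mode, job$ag, job$calib, job$rule)
  rendered <- clip_check(rendered)
  meta <- list(
    input = job$input, mode = job$mode, env = job$sc$kind,
    snr_db = job$sc$snr_db, distance = job$sc$distance,
    distance_unit = job$sc$distance_unit, seed = job$seed,
    rate = rendered$rate, input_spl = job$input_spl,
    output_spl = measure_spl(rendered, job$calib),
    clip_count = attr(rendered, "clip_count"),
    source_id = paste(job$input, job$duration, job$rate, job$seed,
                      sep = "|"))
  if (!is.null(out)) {
    write_wav(rendered, out)
    jsonlite::write_json(meta, paste0(out, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  structure(list(audio = rendered, meta = meta, out = out),
            class = "render_result")
}

#' @export
print.render_result <- function(x, ...) {
  cat(sprintf("<render_result> mode=%s env=%s  %.1f dB SPL out, %d clipped\n",
              x$meta$mode, x$meta$env, x$meta$output_spl, x$meta$clip_count))
  invisible(x)
}

#' Compare renders of the same source across modes
#'
#' Tabulates, per render: broadband SPL, mixed-in SNR (if any), and the
#' broadband and per-band deltas against the `"normal"` render of the same
#' source. All renders must share the same source (input, duration, rate,
#' seed).
#'
#' @param results A named list of `render_result`s (>= 2), at least one with
#'   mode `"normal"` for the deltas.
#' @param calib A `calibration_map` for the band analysis.
#' @return A list of class `compare_report`: `summary` (tibble: label, mode,
#'   env, spl_db, snr_db, delta_db) and `bands` (long tibble: label, band,
#'   level_db, delta_db).
#' @export
compare_report <- function(results, calib = default_calibration()) {
  if (length(results) < 2)
    stop("compare_report needs at least 2 renders", call. = FALSE)
  if (is.null(names(results)))
    names(results) <- vapply(results, function(r) r$meta$mode, character(1))
  ids <- vapply(results, function(r) r$meta$source_id, character(1))
  if (length(unique(ids)) != 1L)
    stop("all renders must share the same source (input/duration/rate/seed)",
         call. = FALSE)
  modes <- vapply(results, function(r) r$meta$mode, character(1))
  ref_i <- match("normal", modes)
  if (is.na(ref_i))
    stop("compare_report needs a 'normal' render as reference", call. = FALSE)
  lv <- lapply(results, function(r) band_levels_spl(r$audio, calib))
  centers <- third_octave_nominal()
  summary <- tibble::tibble(
    label = names(results),
    mode = unname(modes),
    env = unname(vapply(results, function(r) r$meta$env, character(1))),
    spl_db = unname(vapply(results, function(r) r$meta$output_spl, numeric(1))),
    snr_db = unname(vapply(results, function(r)
      if (is.null(r$meta$snr_db)) NA_real_ else r$meta$snr_db, numeric(1))))
  summary$delta_db <- summary$spl_db - summary$spl_db[ref_i]
  bands <- do.call(rbind, lapply(seq_along(results), function(i) {
    tibble::tibble(label = names(results)[i], band = centers,
                   level_db = lv[[i]], delta_db = lv[[i]] - lv[[ref_i]])
  }))
  structure(list(summary = summary, bands = bands), class = "compare_report")
}

#' @export
print.compare_report <- function(x, ...) {
  cat("<compare_report>\n")
  print(x$summary)
  invisible(x)
}

#' Plot a compare report
#'
#' Per-band levels of each render, the counseling-demonstration view of how
#' the profiles differ across frequency.
#' @param object A `compare_report`.
#' @param ... Unused.
#' @export
autoplot.compare_report <- function(object, ...) {
  ggplot2::ggplot(object$bands,
                  ggplot2::aes(x = .data$band, y = .data$level_db,
                               colour = .data$label)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10(breaks = c(125, 250, 500, 1000, 2000, 4000, 8000)) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Band level (dB SPL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
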