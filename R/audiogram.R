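#' Audiograms
#'
#' An audiogram holds per-ear hearing thresholds in dB HL at audiometric
#' frequencies and parameterizes both the unaided-loss and hearing-aid
#' stages. Ears are independent and may differ. The required frequency set
#' is the standard octave series 250--8000 Hz; inter-octave points
#' (125, 750, 1500, 3000, 6000 Hz) are optional.
#'
#' @param left,right Named numeric vectors of thresholds (dB HL) with
#'   frequencies (Hz) as names, e.g. `c("250" = 15, "500" = 20, ...)`.
#' @return An object of class `audiogram` with elements `left` and `right`,
#'   each a data frame with columns `freq` (Hz, strictly ascending) and
#'   `threshold` (dB HL).
#' @export
audiogram <- function(left, right = left) {
  parse_ear <- function(v, ear) {
    if (is.null(names(v)) || any(names(v) == ""))
      stop(ear, ": thresholds must be named by frequency (Hz)", call. = FALSE)
    freq <- suppressWarnings(as.numeric(names(v)))
    if (any(is.na(freq)))
      stop(ear, ": non-numeric frequency key", call. = FALSE)
    thr <- as.numeric(v)
    if (length(freq) < 2)
      stop(ear, ": at least 2 frequency points required", call. = FALSE)
    if (any(diff(freq) <= 0))
      stop(ear, ": frequencies must be strictly ascending", call. = FALSE)
    if (any(freq < 125 | freq > 12000))
      stop(ear, ": frequencies must lie in [125, 12000] Hz", call. = FALSE)
    if (any(!is.finite(thr)) || any(thr < -10 | thr > 120))
      stop(ear, ": thresholds must lie in [-10, 120] dB HL", call. = FALSE)
    data.frame(freq = freq, threshold = thr)
  }
  structure(list(left = parse_ear(left, "left"),
                 right = parse_ear(right, "right")),
            class = "audiogram")
}

#' @export
print.audiogram <- function(x, ...) {
  cat("<audiogram> dB HL thresholds\n")
  for (ear in c("left", "right")) {
    cat(sprintf("  %-5s %s\n", ear,
                paste(sprintf("%g:%g", x[[ear]]$freq, x[[ear]]$threshold),
                      collapse = "  ")))
  }
  invisible(x)
}

#' Load / save an audiogram as JSON
#'
#' The on-disk schema is
#' `{"left": {"<freqHz>": <dB HL>, ...}, "right": {...}}` with numeric-string
#' keys; the writer emits keys in ascending frequency order, so a
#' load-save-load round trip is value-identical.
#'
#' @param path Path to a JSON file.
#' @return `load_audiogram()`: a validated `audiogram`.
#' @export
load_audiogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path)
  for (ear in c("left", "right"))
    if (is.null(obj[[ear]]))
      stop("audiogram JSON missing required field: ", ear, call. = FALSE)
  audiogram(unlist(obj$left), unlist(obj$right))
}

#' @rdname load_audiogram
#' @param ag An `audiogram`.
#' @export
save_audiogram <- function(ag, path) {
  as_map <- function(df) {
    o <- order(df$freq)
    stats::setNames(as.list(df$threshold[o]), format(df$freq[o], scientific = FALSE))
  }
  jsonlite::write_json(list(left = as_map(ag$left), right = as_map(ag$right)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Registered presets, stored as data so they are trivially replaceable.
# "sloping_snhl" is a typical mild-sloping-to-severe presbycusis shape,
# symmetric across ears.
.audiogram_presets <- list(
  normal = c("250" = 0, "500" = 0, "1000" = 0, "2000" = 0,
             "4000" = 0, "8000" = 0),
  sloping_snhl = c("250" = 15, "500" = 20, "1000" = 30, "2000" = 45,
                   "4000" = 60, "8000" = 70)
)

#' Audiogram presets
#'
#' `"normal"` is all-zero thresholds; `"sloping_snhl"` is the sloping
#' sensorineural configuration used for demonstrations (monotonically
#' non-decreasing with frequency, symmetric ears).
#' @param name Preset identifier.
#' @export
audiogram_preset <- function(name) {
  if (!name %in% names(.audiogram_presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.audiogram_presets), collapse = ", "), call. = FALSE)
  v <- .audiogram_presets[[name]]
  audiogram(v, v)
}

#' @rdname audiogram_preset
#' @export
list_presets <- function() names(.audiogram_presets)

#' Interpolate audiogram thresholds onto filterbank band centers
#'
#' Linear interpolation of dB HL against log2(frequency) — the audiogram
#' plotting convention — with flat (nearest-endpoint) extrapolation outside
#' the audiogram's span, so extreme losses are never extrapolated.
#'
#' @param ag An `audiogram`.
#' @param ear `"left"` or `"right"`.
#' @param centers Band center frequencies (Hz), ascending, within
#'   \[50, 16000\] Hz.
#' @return Numeric vector of thresholds (dB HL), one per center.
#' @export
interpolate_to_bands <- function(ag, ear = c("left", "right"), centers) {
  ear <- match.arg(ear)
  if (length(centers) == 0) stop("centers must be non-empty", call. = FALSE)
  if (any(diff(centers) <= 0)) stop("centers must be strictly ascending", call. = FALSE)
  if (any(centers < 50 | centers > 16000))
    stop("centers must lie in [50, 16000] Hz", call. = FALSE)
  e <- ag[[ear]]
  stats::approx(x = log2(e$freq), y = e$threshold, xout = log2(centers),
                method = "linear", rule = 2)$y
}
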