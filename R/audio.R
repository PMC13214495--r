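#' Audio buffers
#'
#' An `audio_buffer` is the package's processing currency: a matrix of
#' full-scale samples (one column per channel, values nominally in
#' \[-1, 1\]) plus a sample rate. Stereo buffers carry independent left/right
#' ear paths (column 1 = left, column 2 = right).
#'
#' @param samples Numeric vector (mono) or matrix with 1 or 2 columns.
#' @param rate Sample rate in Hz; one of 16000, 22050, 32000, 44100, 48000.
#' @return An object of class `audio_buffer`.
#' @export
audio_buffer <- function(samples, rate) {
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric vector or matrix", call. = FALSE)
  if (!ncol(samples) %in% c(1L, 2L))
    stop("audio_buffer supports 1 (mono) or 2 (stereo L/R) channels", call. = FALSE)
  if (nrow(samples) < 1L) stop("audio_buffer needs at least one sample", call. = FALSE)
  if (!all(is.finite(samples))) stop("samples must be finite", call. = FALSE)
  rate <- as.integer(rate)
  if (!rate %in% c(16000L, 22050L, 32000L, 44100L, 48000L))
    stop("unsupported sample rate: ", rate, call. = FALSE)
  structure(list(samples = samples, rate = rate), class = "audio_buffer")
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("<audio_buffer> %d samples, %d channel(s), %d Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              nrow(x$samples) / x$rate))
  invisible(x)
}

#' Buffer dimensions
#' @param x An `audio_buffer`.
#' @export
n_channels <- function(x) ncol(x$samples)

#' @rdname n_channels
#' @export
n_samples <- function(x) nrow(x$samples)

#' Extract one channel as a mono buffer
#' @param x An `audio_buffer`.
#' @param channel Column index (1 = left, 2 = right).
#' @export
mono_channel <- function(x, channel = 1L) {
  audio_buffer(x$samples[, channel], x$rate)
}

#' Reduce to mono / expand to stereo
#'
#' `to_mono()` averages channels (the simulator models one sound field heard
#' by two ears); `to_stereo()` duplicates a mono buffer onto both ear paths.
#' @param x An `audio_buffer`.
#' @export
to_mono <- function(x) {
  if (n_channels(x) == 1L) return(x)
  audio_buffer(rowMeans(x$samples), x$rate)
}

#' @rdname to_mono
#' @export
to_stereo <- function(x) {
  if (n_channels(x) == 2L) return(x)
  audio_buffer(cbind(x$samples[, 1], x$samples[, 1]), x$rate)
}

#' Root-mean-square amplitude of a buffer
#' @param x An `audio_buffer`.
#' @param channel Optional channel index; default pools all channels.
#' @return RMS amplitude (full-scale units).
#' @export
buffer_rms <- function(x, channel = NULL) {
  s <- if (is.null(channel)) x$samples else x$samples[, channel, drop = FALSE]
  sqrt(mean(s^2))
}

#' Scale a buffer by a linear factor or to a target RMS
#' @param x An `audio_buffer`.
#' @param target_rms Desired RMS amplitude (full-scale).
#' @export
scale_to_rms <- function(x, target_rms) {
  r <- buffer_rms(x)
  if (r <= 0) stop("cannot scale a silent buffer", call. = FALSE)
  audio_buffer(x$samples * (target_rms / r), x$rate)
}

# Hard-clip to [-1, 1]; warn with the clip count (aided paths may clip).
clip_check <- function(x, warn = TRUE) {
  n_clip <- sum(abs(x$samples) > 1)
  if (n_clip > 0) {
    x$samples <- clamp(x$samples, -1, 1)
    if (warn) warning(sprintf("%d sample(s) clipped to full scale", n_clip),
                      call. = FALSE)
  }
  attr(x, "clip_count") <- n_clip
  x
}

## ---- WAV I/O (RIFF/WAVE, PCM16/24 and IEEE float32) -----------------------

#' Read a WAV file
#'
#' Supports PCM 16/24-bit and IEEE float32, mono or stereo.
#' @param path Path to a `.wav` file.
#' @return An `audio_buffer`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format    = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels  = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate      = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits      = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2)  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("WAV file missing fmt/data chunk: ", path, call. = FALSE)
  samples <- switch(as.character(fmt$format),
    "1" = {  # integer PCM
      if (fmt$bits == 16) {
        readBin(data_raw, "integer", length(data_raw) / 2, 2,
                signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 24) {
        b <- as.integer(data_raw)
        n <- length(b) / 3
        idx <- 3 * (seq_len(n) - 1)
        v <- b[idx + 1] + 256 * b[idx + 2] + 65536 * b[idx + 3]
        v <- ifelse(v >= 2^23, v - 2^24, v)
        v / 2^23
      } else stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
    },
    "3" = {  # IEEE float
      if (fmt$bits != 32) stop("unsupported float bit depth: ", fmt$bits, call. = FALSE)
      readBin(data_raw, "numeric", length(data_raw) / 4, 4, endian = "little")
    },
    stop("unsupported WAV format code: ", fmt$format, call. = FALSE))
  audio_buffer(matrix(samples, ncol = fmt$channels, byrow = TRUE), fmt$rate)
}

#' Write a WAV file
#'
#' Defaults to IEEE float32 so passthrough contracts are not degraded by
#' quantization; PCM16 is available for interchange.
#' @param x An `audio_buffer`.
#' @param path Output path.
#' @param format `"float32"` (default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  interleaved <- as.numeric(t(x$samples))
  ch <- n_channels(x)
  if (format == "float32") {
    fmt_code <- 3L; bits <- 32L
    payload_n <- length(interleaved) * 4L
  } else {
    fmt_code <- 1L; bits <- 16L
    payload_n <- length(interleaved) * 2L
  }
  block_align <- ch * bits / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + payload_n), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(as.integer(ch), con, 2, endian = "little")
  writeBin(as.integer(x$rate), con, 4, endian = "little")
  writeBin(as.integer(x$rate * block_align), con, 4, endian = "little")
  writeBin(as.integer(block_align), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(payload_n), con, 4, endian = "little")
  if (format == "float32") {
    writeBin(interleaved, con, 4, endian = "little")
  } else {
    q <- as.integer(clamp(round(interleaved * 32768), -32768, 32767))
    writeBin(q, con, 2, endian = "little")
  }
  invisible(path)
}
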