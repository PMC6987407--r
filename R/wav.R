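#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for PCM (8/16/24/32-bit integer) and IEEE
#' float32 data, returning samples scaled to [-1, 1]. Multichannel files are
#' rejected unless a channel is selected explicitly. Optionally resamples to
#' a target rate (polyphase resampling).
#'
#' @param path WAV file path.
#' @param target_fs optional target sampling rate in Hz.
#' @param channel `"error"` (reject multichannel input), or a channel number
#'   to extract.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path, target_fs = NULL, channel = "error") {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")  # overall size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, FALSE, "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, FALSE, "little"),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2, FALSE, "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2)  # skip (chunks are word-aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("missing fmt/data chunk in ", path, call. = FALSE)
  }

  bytes <- fmt$bits %/% 8
  n_total <- length(data_raw) %/% bytes
  x <- if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", n_total, 4, endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n_total, 2, TRUE, "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 8L) {
    (readBin(data_raw, "integer", n_total, 1, FALSE, "little") - 128) / 128
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    ifelse(v >= 2^23, v - 2^24, v) / 2^23
  } else if (fmt$audio_format == 1L && fmt$bits == 32L) {
    readBin(data_raw, "integer", n_total, 4, TRUE, "little") / 2^31
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d-bit)",
                 fmt$audio_format, fmt$bits), call. = FALSE)
  }

  if (fmt$channels > 1L) {
    if (identical(channel, "error")) {
      stop(sprintf("%s has %d channels; mono required (pass channel = <k>)",
                   path, fmt$channels), call. = FALSE)
    }
    x <- matrix(x, nrow = fmt$channels)[as.integer(channel), ]
  }
  out <- audio_signal(x, fmt$sample_rate)
  if (!is.null(target_fs) && target_fs != out$sample_rate) {
    out <- resample_audio(out, target_fs)
  }
  out
}

#' Write a mono WAV file
#'
#' @param x an [audio_signal()]; samples are clipped to [-1, 1].
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bits = 16) {
  x <- as_audio(x)
  s <- pmin(pmax(x$samples, -1), 1)
  fs <- as.integer(round(x$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  if (bits == 16) {
    fmt_code <- 1L; bytes <- 2L
    payload <- as.integer(round(s * 32767))
  } else if (bits == 32) {
    fmt_code <- 3L; bytes <- 4L
    payload <- s
  } else stop("`bits` must be 16 or 32", call. = FALSE)
  data_size <- length(s) * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")              # mono
  writeBin(fs, con, 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, 4, endian = "little")
  writeBin(bytes, con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    writeBin(payload, con, 2, endian = "little")
  } else {
    writeBin(payload, con, 4, endian = "little")
  }
  invisible(path)
}

#' Resample an audio signal
#'
#' Rational-ratio polyphase resampling via the signal package.
#'
#' @param x an [audio_signal()].
#' @param target_fs target rate in Hz.
#' @return An [audio_signal()] at `target_fs`.
#' @export
resample_audio <- function(x, target_fs) {
  x <- as_audio(x)
  if (target_fs == x$sample_rate) return(x)
  frac <- rational_approx(target_fs / x$sample_rate)
  y <- signal::resample(x$samples, frac[1], frac[2])
  audio_signal(as.numeric(y), target_fs)
}

rational_approx <- function(r, max_den = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { best <- c(as.integer(p), q); err <- e }
    if (err < 1e-12) break
  }
  best
}
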