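#' Framing configuration
#'
#' Frame geometry for log-energy spectrograms: a 30 ms window advanced by a
#' 15 ms stride by default, with an energy floor that keeps silent frames
#' finite.
#'
#' @param fs sampling rate in Hz (used to convert seconds to samples).
#' @param window_s window length in seconds (default 0.030).
#' @param stride_s hop between frames in seconds (default half the window).
#' @param e_floor minimum frame energy in dB; silent frames report this value
#'   instead of -Inf.
#' @return A `framing_config` with `l` (window samples), `stride` (samples),
#'   their durations in seconds, and `e_floor`.
#' @export
framing_config <- function(fs, window_s = 0.030, stride_s = window_s / 2,
                           e_floor = -100) {
  stop_if_not_scalar_number(fs, "fs")
  stop_if_not_scalar_number(window_s, "window_s")
  stop_if_not_scalar_number(stride_s, "stride_s")
  l <- as.integer(round(window_s * fs))
  stride <- as.integer(round(stride_s * fs))
  if (l < 1L || stride < 1L || stride > l) {
    stop("need 0 < stride <= window length", call. = FALSE)
  }
  structure(
    list(fs = fs, l = l, stride = stride,
         window_s = l / fs, stride_s = stride / fs, e_floor = e_floor),
    class = "framing_config"
  )
}

#' Log frame energy of one sequence
#'
#' Slides a window of `l` samples by the stride and reports
#' `10 * log10(sum(x^2))` per frame, floored at `e_floor`. Frame time stamps
#' are window centres in seconds.
#'
#' @param x numeric sequence (one sub-band waveform).
#' @param framing a [framing_config()].
#' @return A list with `energy` (dB vector) and `times` (seconds).
#' @export
frame_energy <- function(x, framing) {
  stopifnot(inherits(framing, "framing_config"))
  m <- length(x)
  l <- framing$l
  stride <- framing$stride
  if (m < l) {
    warning("signal shorter than one window; right-padding with zeros")
    x <- c(x, numeric(l - m))
    m <- l
  }
  n_frames <- (m - l) %/% stride + 1L
  starts <- (seq_len(n_frames) - 1L) * stride  # 0-based start sample
  e <- vapply(starts, function(s) sum(x[(s + 1L):(s + l)]^2), numeric(1))
  e_db <- ifelse(e > 0, 10 * log10(e), -Inf)
  e_db <- pmax(e_db, framing$e_floor)
  list(energy = e_db, times = (starts + (l - 1) / 2) / framing$fs)
}

#' Cochlear log-energy spectrogram
#'
#' Runs [analyze()] then [frame_energy()] on every channel: the K x N matrix
#' of per-channel frame energies in dB that the masking model and the
#' pattern-path encoder consume.
#'
#' @param x an [audio_signal()].
#' @param bank a [build_filterbank()] result.
#' @param framing a [framing_config()]; defaults to 30 ms / 15 ms at the
#'   bank's sampling rate.
#' @return A `spectrogram`: `energies` (K x N dB matrix), `frame_times`
#'   (seconds, window centres), `centres` (channel centre frequencies, Hz),
#'   plus the framing and sampling rate.
#' @export
spectrogram <- function(x, bank, framing = NULL) {
  x <- as_audio(x)
  stopifnot(inherits(bank, "filter_bank"))
  if (is.null(framing)) framing <- framing_config(bank$fs)
  sub <- analyze(x, bank)
  first <- frame_energy(sub[1, ], framing)
  K <- nrow(sub)
  energies <- matrix(framing$e_floor, K, length(first$energy))
  energies[1, ] <- first$energy
  if (K > 1) {
    for (k in 2:K) energies[k, ] <- frame_energy(sub[k, ], framing)$energy
  }
  rownames(energies) <- rownames(sub)
  structure(
    list(energies = energies, frame_times = first$times,
         centres = bank$specs$centre, framing = framing, fs = bank$fs,
         duration = length(x$samples) / x$sample_rate),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram: %d channels x %d frames, %.3f s, energy %.1f..%.1f dB>\n",
    nrow(x$energies), ncol(x$energies), x$duration,
    min(x$energies), max(x$energies)
  ))
  invisible(x)
}
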