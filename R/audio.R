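#' Audio signal container
#'
#' Bundles a mono sample vector with its sampling rate. All codec operations
#' accept and return `audio_signal` objects; samples are amplitude values on a
#' nominal full-scale of +/- 1.
#'
#' @param samples numeric vector of mono samples.
#' @param sample_rate sampling rate in Hz.
#' @return An object of class `audio_signal` with fields `samples` and
#'   `sample_rate`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 440 * (0:999) / 16000), 16000)
#' duration(x)
#' @export
audio_signal <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  stop_if_not_scalar_number(sample_rate, "sample_rate")
  if (sample_rate <= 0) stop("`sample_rate` must be positive", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal: %d samples @ %g Hz (%.3f s), peak %.3f>\n",
    length(x$samples), x$sample_rate,
    length(x$samples) / x$sample_rate, max(abs(x$samples))
  ))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param x an `audio_signal`.
#' @return Length in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$sample_rate
}

as_audio <- function(x) {
  if (inherits(x, "audio_signal")) return(x)
  stop("expected an `audio_signal`; see audio_signal()", call. = FALSE)
}
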