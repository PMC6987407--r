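#' Spike pattern container
#'
#' A sparse set of (neuron, time) events produced by one of the encoders.
#' Events carry the channel, the neuron kind (`onset`, `offset`, `peak` or
#' `latency`), the threshold-level index, and — on the waveform path — the
#' amplitude of the crossed level, which the decoder interpolates through.
#'
#' @param events data.frame with columns `neuron` (0-based), `time`
#'   (seconds), `channel`, `kind`, `level`, `amplitude`.
#' @param duration pattern duration in seconds.
#' @param fs sampling rate of the encoded signal, Hz.
#' @param path `"pattern"` (frame-energy trajectories) or `"waveform"`
#'   (sub-band level crossings).
#' @param provenance `"raw"`, `"masked"`, `"random"` or `"2xthreshold"`.
#' @param neurons total neuron population size of the encoder.
#' @param levels the level amplitudes used (per-channel list on the waveform
#'   path, normalized thresholds on the pattern path).
#' @return A `spike_pattern` object; events are kept sorted by time.
#' @export
spike_pattern <- function(events, duration, fs, path, provenance = "raw",
                          neurons = NA_integer_, levels = NULL) {
  cols <- c("neuron", "time", "channel", "kind", "level", "amplitude")
  if (nrow(events) == 0L) {
    events <- data.frame(neuron = integer(), time = numeric(),
                         channel = integer(), kind = character(),
                         level = integer(), amplitude = numeric())
  }
  stopifnot(all(cols %in% names(events)))
  events <- events[order(events$time, events$neuron), cols, drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events) > 0 &&
      (min(events$time) < 0 || max(events$time) > duration + 1e-9)) {
    stop("event times must lie within [0, duration]", call. = FALSE)
  }
  structure(
    list(events = events, duration = duration, fs = fs, path = path,
         provenance = provenance, neurons = neurons, levels = levels),
    class = "spike_pattern"
  )
}

#' @export
print.spike_pattern <- function(x, ...) {
  cat(sprintf(
    "<spike_pattern [%s/%s]: %d events, %d neurons, %.3f s (%.0f spikes/s)>\n",
    x$path, x$provenance, nrow(x$events), x$neurons, x$duration,
    nrow(x$events) / max(x$duration, .Machine$double.eps)
  ))
  invisible(x)
}

#' Number of spike events in a pattern
#' @param pattern a [spike_pattern()].
#' @return Integer event count.
#' @export
n_events <- function(pattern) {
  stopifnot(inherits(pattern, "spike_pattern"))
  nrow(pattern$events)
}
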