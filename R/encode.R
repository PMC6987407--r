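#' Uniform threshold set for the pattern-path encoder
#'
#' `L` uniformly spaced levels strictly inside the normalized (0, 1) energy
#' range: `theta_n = n / (L + 1)`. The default population uses 15 levels per
#' channel.
#'
#' @param L number of levels.
#' @param mode `"per-utterance"` (min-max normalize each spectrogram to
#'   [0, 1] before encoding) or `"fixed-range"` (use `range` as the dB range
#'   mapped onto [0, 1]).
#' @param range two dB values used by `"fixed-range"` normalization.
#' @return A `threshold_set` with strictly increasing `levels`.
#' @export
threshold_set <- function(L = 15, mode = c("per-utterance", "fixed-range"),
                          range = c(-100, 20)) {
  stop_if_not_scalar_number(L, "L")
  if (L < 1) stop("`L` must be >= 1", call. = FALSE)
  structure(
    list(levels = seq_len(L) / (L + 1), L = as.integer(L),
         mode = match.arg(mode), range = range),
    class = "threshold_set"
  )
}

#' Encoding-neuron population map
#'
#' Ties each neuron index to a (channel, level, polarity) triple. The default
#' `"tidigits-620"` preset allocates, per channel, one onset and one offset
#' neuron per threshold level plus one peak neuron: with 20 channels and 15
#' levels that is 20 x 31 = 620 encoding neurons.
#'
#' @param K number of channels.
#' @param L number of threshold levels.
#' @param peak include a per-channel peak neuron.
#' @param preset `"tidigits-620"` fixes K = 20, L = 15, peak = TRUE;
#'   `"custom"` uses the arguments as given.
#' @return A data.frame (class `neuron_map`) with columns `neuron` (0-based),
#'   `channel`, `kind`, `level`.
#' @export
neuron_map <- function(K = 20, L = 15, peak = TRUE,
                       preset = c("tidigits-620", "custom")) {
  preset <- match.arg(preset)
  if (preset == "tidigits-620") {
    K <- 20L; L <- 15L; peak <- TRUE
  }
  per <- 2L * L + as.integer(peak)
  rows <- lapply(seq_len(K), function(k) {
    base <- (k - 1L) * per
    d <- data.frame(
      neuron = base + seq_len(2L * L) - 1L,
      channel = k,
      kind = rep(c("onset", "offset"), each = L),
      level = c(seq_len(L), seq_len(L))
    )
    if (peak) {
      d <- rbind(d, data.frame(neuron = base + 2L * L, channel = k,
                               kind = "peak", level = NA_integer_))
    }
    d
  })
  out <- do.call(rbind, rows)
  class(out) <- c("neuron_map", class(out))
  attr(out, "K") <- K
  attr(out, "L") <- L
  attr(out, "per_channel") <- per
  out
}

# Upward crossings of level th in piecewise-linear trajectory v over times t.
# Tie rule: a crossing counts on its arrival side only
# (up: v[j] < th <= v[j+1]; down: v[j] > th >= v[j+1]).
crossing_times <- function(v, t, th, direction) {
  n <- length(v)
  if (n < 2L) return(numeric(0))
  a <- v[-n]; b <- v[-1]
  hit <- if (direction == "up") a < th & b >= th else a > th & b <= th
  j <- which(hit)
  if (length(j) == 0L) return(numeric(0))
  frac <- (th - a[j]) / (b[j] - a[j])
  t[j] + frac * (t[j + 1] - t[j])
}

#' Threshold coding of a spectrogram (pattern path)
#'
#' Treats each channel's frame-energy sequence as a piecewise-linear
#' trajectory over frame-centre times and emits precise spike times where it
#' crosses each threshold level: upward crossings fire that level's onset
#' neuron, downward crossings its offset neuron, and each interior local
#' maximum fires the channel's peak neuron at the peak's frame time.
#' Crossing times are linearly interpolated between the bracketing frames.
#'
#' @param spec a [spectrogram()].
#' @param thresholds a [threshold_set()].
#' @param map a [neuron_map()] whose K and L match `spec` and `thresholds`.
#' @return A pattern-path [spike_pattern()].
#' @export
threshold_encode <- function(spec, thresholds = threshold_set(),
                             map = neuron_map()) {
  stopifnot(inherits(spec, "spectrogram"), inherits(thresholds, "threshold_set"))
  K <- nrow(spec$energies)
  if (attr(map, "K") != K) {
    stop("neuron map channel count does not match spectrogram", call. = FALSE)
  }
  if (attr(map, "L") < thresholds$L) {
    stop("neuron map has fewer levels than the threshold set", call. = FALSE)
  }
  v <- normalize_energies(spec$energies, thresholds)
  t <- spec$frame_times
  per <- attr(map, "per_channel")
  has_peak <- per > 2L * attr(map, "L")
  Lmap <- attr(map, "L")
  acc <- event_accumulator()
  for (k in seq_len(K)) {
    base <- (k - 1L) * per
    for (n in seq_len(thresholds$L)) {
      th <- thresholds$levels[n]
      acc$add(base + n - 1L, crossing_times(v[k, ], t, th, "up"),
              k, "onset", n, th)
      acc$add(base + Lmap + n - 1L, crossing_times(v[k, ], t, th, "down"),
              k, "offset", n, th)
    }
    if (has_peak && ncol(v) >= 3L) {
      mid <- 2:(ncol(v) - 1L)
      pk <- mid[v[k, mid] > v[k, mid - 1L] & v[k, mid] > v[k, mid + 1L]]
      if (length(pk)) {
        acc$add(base + 2L * Lmap, t[pk], k, "peak", NA_integer_, v[k, pk])
      }
    }
  }
  events <- acc$collect()
  spike_pattern(events, duration = spec$duration, fs = spec$fs,
                path = "pattern", provenance = "raw",
                neurons = K * per, levels = thresholds$levels)
}

normalize_energies <- function(e, thresholds) {
  if (thresholds$mode == "per-utterance") {
    lo <- min(e); hi <- max(e)
  } else {
    lo <- thresholds$range[1]; hi <- thresholds$range[2]
  }
  if (hi <= lo) return(matrix(0, nrow(e), ncol(e)))
  pmin(pmax((e - lo) / (hi - lo), 0), 1)
}

#' Latency-coding configuration
#'
#' Single-neuron-per-channel baseline: frame energy `e` (normalized to
#' [0, 1]) is represented by spike delay within an encoding window of length
#' `T`; the n-th spike of a frame lands at `(n - e) * T` after the frame
#' start.
#'
#' @param window_s encoding window T in seconds (default one frame stride).
#' @param order number of spikes per window.
#' @export
latency_config <- function(window_s = 0.015, order = 1L) {
  stop_if_not_scalar_number(window_s, "window_s")
  if (window_s <= 0) stop("`window_s` must be > 0", call. = FALSE)
  structure(list(window_s = window_s, order = as.integer(order)),
            class = "latency_config")
}

#' Latency coding of a spectrogram (baseline)
#'
#' One neuron per channel; each frame emits `order` spikes whose delays
#' encode the normalized frame energy: spike n at frame start plus
#' `(n - e) * T`. Strong frames fire early.
#'
#' @param spec a [spectrogram()].
#' @param cfg a [latency_config()].
#' @param thresholds a [threshold_set()]; only its normalization mode is
#'   used.
#' @return A pattern-path [spike_pattern()] with `kind = "latency"`.
#' @export
latency_encode <- function(spec, cfg = latency_config(),
                           thresholds = threshold_set()) {
  stopifnot(inherits(spec, "spectrogram"), inherits(cfg, "latency_config"))
  v <- normalize_energies(spec$energies, thresholds)
  half_win <- (spec$framing$l - 1) / 2 / spec$fs
  starts <- spec$frame_times - half_win
  K <- nrow(v); N <- ncol(v)
  ev <- list()
  for (n in seq_len(cfg$order)) {
    times <- sweep(matrix((n - v) * cfg$window_s, K, N), 2, starts, "+")
    ev[[n]] <- data.frame(
      neuron = rep(seq_len(K) - 1L, N), time = as.vector(times),
      channel = rep(seq_len(K), N), kind = "latency",
      level = n, amplitude = as.vector(v))
  }
  events <- do.call(rbind, ev)
  dur <- max(spec$duration, max(events$time))
  spike_pattern(events, duration = dur, fs = spec$fs, path = "pattern",
                provenance = "raw", neurons = K, levels = NULL)
}
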