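#' Level-crossing coding of sub-band waveforms (waveform path)
#'
#' Encodes each sub-band waveform into spike events at every crossing of a
#' set of amplitude levels, with sub-sample linear interpolation of the
#' crossing time. Upward crossings are onset events, downward crossings
#' offset events; each event carries the crossed level's amplitude, which is
#' what makes waveform reconstruction possible. By default `L` levels are
#' placed uniformly strictly inside each channel's amplitude range
#' (per-utterance); a shared explicit `levels` vector may be supplied
#' instead. Channels whose amplitude range is numerically zero emit no
#' events.
#'
#' @param subbands K x M matrix of sub-band waveforms (rows = channels), as
#'   returned by [analyze()].
#' @param fs sampling rate in Hz.
#' @param L number of levels per channel (default 31).
#' @param levels optional numeric vector of explicit level amplitudes used
#'   for every channel (overrides `L`).
#' @return A waveform-path [spike_pattern()]; `levels` holds the per-channel
#'   level amplitudes.
#' @export
level_crossing_encode <- function(subbands, fs, L = 31, levels = NULL) {
  if (is.numeric(subbands) && is.null(dim(subbands))) {
    subbands <- matrix(subbands, nrow = 1)
  }
  stopifnot(is.matrix(subbands))
  stop_if_not_scalar_number(fs, "fs")
  K <- nrow(subbands); M <- ncol(subbands)
  t_axis <- (seq_len(M) - 1) / fs
  level_list <- vector("list", K)
  acc <- event_accumulator()
  for (k in seq_len(K)) {
    x <- subbands[k, ]
    lv <- if (is.null(levels)) channel_levels(x, L) else sort(levels)
    level_list[[k]] <- lv
    base <- (k - 1L) * 2L * length(lv)
    for (n in seq_along(lv)) {
      up <- crossing_times(x, t_axis, lv[n], "up")
      dn <- crossing_times(x, t_axis, lv[n], "down")
      acc$add(base + 2L * (n - 1L), up, k, "onset", n, lv[n])
      acc$add(base + 2L * (n - 1L) + 1L, dn, k, "offset", n, lv[n])
    }
  }
  events <- acc$collect()
  n_lv <- if (is.null(levels)) L else length(levels)
  spike_pattern(events, duration = M / fs, fs = fs, path = "waveform",
                provenance = "raw", neurons = K * 2L * n_lv,
                levels = level_list)
}

# L levels uniformly spaced strictly inside [min(x), max(x)].
channel_levels <- function(x, L) {
  lo <- min(x); hi <- max(x)
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < 1e-12) return(numeric(0))
  seq(lo, hi, length.out = L + 2L)[-c(1L, L + 2L)]
}

#' Doubled-threshold baseline encoder
#'
#' Re-encodes with every second level of the base level set (half as many
#' levels across the same range), the energy-only masking baseline used to
#' contrast against perceptual masking. Accepts either a spectrogram (pattern
#' path) or a sub-band matrix (waveform path).
#'
#' @param x a [spectrogram()] or K x M sub-band matrix.
#' @param fs sampling rate (waveform path only).
#' @param L base level count before doubling the spacing.
#' @param thresholds base [threshold_set()] (pattern path only).
#' @param map a [neuron_map()] (pattern path only).
#' @return A [spike_pattern()] with provenance `"2xthreshold"`.
#' @export
doubled_threshold_encode <- function(x, fs = NULL, L = 31,
                                     thresholds = threshold_set(),
                                     map = neuron_map()) {
  if (inherits(x, "spectrogram")) {
    keep <- seq(1L, thresholds$L, by = 2L)
    sub <- thresholds
    sub$levels <- thresholds$levels[keep]
    sub$L <- length(keep)
    pat <- threshold_encode(x, sub, map)
    # re-tag events with their base-set level indices
    pat$events$level <- keep[pat$events$level]
    pat$provenance <- "2xthreshold"
    return(pat)
  }
  if (is.null(fs)) stop("`fs` is required for waveform input", call. = FALSE)
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1)
  K <- nrow(x)
  keep <- seq(1L, L, by = 2L)
  acc <- event_accumulator()
  level_list <- vector("list", K)
  t_axis <- (seq_len(ncol(x)) - 1) / fs
  for (k in seq_len(K)) {
    lv_full <- channel_levels(x[k, ], L)
    lv <- lv_full[keep[keep <= length(lv_full)]]
    level_list[[k]] <- lv
    base <- (k - 1L) * 2L * length(keep)
    for (n in seq_along(lv)) {
      acc$add(base + 2L * (n - 1L),
              crossing_times(x[k, ], t_axis, lv[n], "up"),
              k, "onset", keep[n], lv[n])
      acc$add(base + 2L * (n - 1L) + 1L,
              crossing_times(x[k, ], t_axis, lv[n], "down"),
              k, "offset", keep[n], lv[n])
    }
  }
  events <- acc$collect()
  spike_pattern(events, duration = ncol(x) / fs, fs = fs, path = "waveform",
                provenance = "2xthreshold", neurons = K * 2L * length(keep),
                levels = level_list)
}

#' Delete spikes in masked time-frequency bins
#'
#' The Hadamard product of a spike pattern with the binary audibility map:
#' events whose time-frequency bin is masked (map value 0) are deleted, all
#' others pass unchanged. Frames overlap (30 ms windows, 15 ms stride), so
#' an event generally lies inside two frame windows; it is kept when any
#' covering frame is audible and deleted only when every frame containing
#' it is masked. Events outside the framed time range are assigned to the
#' nearest frame with a warning.
#'
#' @param pattern a [spike_pattern()] (either path).
#' @param map a [masking_map()].
#' @param frames the [spectrogram()] the map was computed from (supplies
#'   frame times and stride).
#' @return The pruned [spike_pattern()] with provenance `"masked"`.
#' @export
apply_mask <- function(pattern, map, frames) {
  stopifnot(inherits(pattern, "spike_pattern"), inherits(map, "masking_map"),
            inherits(frames, "spectrogram"))
  if (nrow(map) < max(pattern$events$channel, 0)) {
    stop("masking map has fewer channels than the pattern", call. = FALSE)
  }
  if (!identical(dim(map), dim(frames$energies))) {
    stop("masking map and spectrogram must share dimensions", call. = FALSE)
  }
  ev <- pattern$events
  out <- pattern
  if (nrow(ev) == 0L) {
    out$provenance <- "masked"
    return(out)
  }
  centres <- frames$frame_times
  half_w <- frames$framing$window_s / 2
  outside <- ev$time < centres[1] - half_w |
    ev$time > centres[length(centres)] + half_w
  if (any(outside)) {
    warning(sprintf("%d event(s) outside the framed range; using nearest frame",
                    sum(outside)))
  }
  # frames containing time t: centres within half a window of t; with a
  # 50% overlap that is the two frames bracketing t (one at the edges)
  lo <- findInterval(ev$time - half_w - 1e-12, centres) + 1L
  hi <- findInterval(ev$time + half_w + 1e-12, centres)
  lo <- pmin(pmax(lo, 1L), length(centres))
  hi <- pmin(pmax(hi, lo), length(centres))
  keep <- logical(nrow(ev))
  for (off in 0:max(hi - lo)) {
    j <- lo + off
    sel <- j <= hi
    keep[sel] <- keep[sel] | map[cbind(ev$channel[sel], j[sel])] == 1
  }
  out$events <- ev[keep, , drop = FALSE]
  rownames(out$events) <- NULL
  out$provenance <- "masked"
  out
}

nearest_frame <- function(t, centres) {
  if (length(centres) == 1L) return(rep(1L, length(t)))
  mids <- (centres[-1] + centres[-length(centres)]) / 2
  findInterval(t, mids) + 1L
}

#' Random spike deletion baseline
#'
#' Uniformly deletes spikes to match a target reduction fraction: exactly
#' `floor(n * (1 - target))` events survive (round-down convention, so the
#' realized reduction is never below the target). Seeded and reproducible;
#' the global RNG state is left untouched.
#'
#' @param pattern a [spike_pattern()].
#' @param target_reduction fraction of events to remove, in [0, 1].
#' @param seed integer RNG seed.
#' @return A [spike_pattern()] with provenance `"random"`.
#' @export
random_mask_baseline <- function(pattern, target_reduction, seed = 1L) {
  stopifnot(inherits(pattern, "spike_pattern"))
  stop_if_not_scalar_number(target_reduction, "target_reduction")
  if (target_reduction < 0 || target_reduction > 1) {
    stop("`target_reduction` must be in [0, 1]", call. = FALSE)
  }
  n <- nrow(pattern$events)
  keep_n <- floor(n * (1 - target_reduction))
  out <- pattern
  keep <- with_local_seed(seed, sort(sample.int(n, keep_n)))
  out$events <- pattern$events[keep, , drop = FALSE]
  rownames(out$events) <- NULL
  out$provenance <- "random"
  out
}
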