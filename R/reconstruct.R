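#' Reconstruction configuration
#'
#' @param interpolation `"linear"` (piecewise-linear through level-crossing
#'   events, the default) or `"zoh"` (zero-order hold).
#' @param synthesis `"matched-filter"` (correlate each channel with its own
#'   cochlear template; paired with the forward-sliding analysis stage the
#'   chain is zero-phase with no net group delay) or `"scalar-gain"` (skip
#'   the synthesis filter, sum gain-weighted estimates directly; faster,
#'   lower fidelity).
#' @param normalize rescale the output to the peak of +/- 1 after summation.
#' @param gap_s event-free stretches longer than this are decoded as
#'   silence: the estimate ramps to zero within `gap_s / 2` after the last
#'   event and back up before the next one, instead of bridging the gap with
#'   one long chord. Level crossings are dense wherever a sub-band carries
#'   signal, so a long silence between events means the channel was quiet
#'   (or its bins were masked) — decoding it as near-zero is the faithful
#'   reading. Default 30 ms; `Inf` disables gap handling.
#' @export
reconstruction_config <- function(interpolation = c("linear", "zoh"),
                                  synthesis = c("matched-filter", "scalar-gain"),
                                  normalize = FALSE, gap_s = 0.030) {
  if (!is.numeric(gap_s) || length(gap_s) != 1L || is.na(gap_s) || gap_s <= 0) {
    stop("`gap_s` must be a positive number (Inf to disable)", call. = FALSE)
  }
  structure(
    list(interpolation = match.arg(interpolation),
         synthesis = match.arg(synthesis), normalize = isTRUE(normalize),
         gap_s = gap_s),
    class = "reconstruction_config"
  )
}

#' Decode a waveform-path spike pattern to sub-band estimates
#'
#' Per channel, interpolates through the (event time, level amplitude) pairs
#' of the level-crossing events; the estimate is zero before the first and
#' after the last event, and channels with fewer than two events are silent.
#'
#' @param pattern a waveform-path [spike_pattern()].
#' @param bank the [build_filterbank()] used for analysis (supplies K and
#'   fs).
#' @param cfg a [reconstruction_config()].
#' @return K x M matrix of sub-band estimates.
#' @export
decode_subbands <- function(pattern, bank, cfg = reconstruction_config()) {
  stopifnot(inherits(pattern, "spike_pattern"), inherits(bank, "filter_bank"))
  if (pattern$path != "waveform") {
    stop(paste("pattern-path (frame-energy) patterns carry no level-tagged",
               "waveform events and cannot be decoded to audio;",
               "encode with level_crossing_encode() instead"), call. = FALSE)
  }
  K <- nrow(bank$specs)
  M <- as.integer(round(pattern$duration * pattern$fs))
  t_axis <- (seq_len(M) - 1) / pattern$fs
  est <- matrix(0, K, M)
  ev <- pattern$events
  method <- if (cfg$interpolation == "linear") "linear" else "constant"
  for (k in seq_len(K)) {
    ek <- ev[ev$channel == k, , drop = FALSE]
    if (nrow(ek) < 2L) next
    ek <- ek[order(ek$time), ]
    anchors <- gap_anchors(ek$time, ek$amplitude, cfg$gap_s)
    y <- stats::approx(anchors$t, anchors$a, xout = t_axis, method = method,
                       yleft = 0, yright = 0, ties = mean)$y
    est[k, ] <- y
  }
  est
}

# Insert zero-amplitude anchors inside event-free stretches longer than
# gap_s, so the estimate decays to silence instead of bridging the gap.
gap_anchors <- function(t, a, gap_s) {
  if (!is.finite(gap_s) || length(t) < 2L) return(list(t = t, a = a))
  dt <- diff(t)
  gaps <- which(dt > gap_s)
  if (length(gaps) == 0L) return(list(t = t, a = a))
  pad <- gap_s / 2
  extra_t <- c(t[gaps] + pad, t[gaps + 1L] - pad)
  ord <- order(c(t, extra_t))
  all_t <- c(t, extra_t)[ord]
  all_a <- c(a, numeric(2L * length(gaps)))[ord]
  list(t = all_t, a = all_a)
}

#' Synthesis filter bank
#'
#' Passes each sub-band estimate through its synthesis filter and sums the
#' channels, weighting each by the bank's calibrated synthesis gain so that
#' unit tones at interior centre frequencies survive the analysis-synthesis
#' round trip with unit amplitude.
#'
#' @param estimates K x M matrix of sub-band estimates.
#' @param bank a [build_filterbank()] result.
#' @param cfg a [reconstruction_config()].
#' @return An [audio_signal()].
#' @export
synthesize <- function(estimates, bank, cfg = reconstruction_config()) {
  stopifnot(is.matrix(estimates), inherits(bank, "filter_bank"))
  K <- nrow(bank$specs)
  if (nrow(estimates) != K) {
    stop("estimate rows must match the bank's channel count", call. = FALSE)
  }
  M <- ncol(estimates)
  out <- numeric(M)
  g <- bank$synthesis_gains
  for (k in seq_len(K)) {
    if (all(estimates[k, ] == 0)) next
    # Matched filtering: correlate with the same cochlear template. The
    # analysis stage slid the taps forward (correlation, transfer conj(H)),
    # so convolving here with the taps (transfer H) makes the chain
    # zero-phase: conj(H) * H = |H|^2, no net group delay.
    ch <- if (cfg$synthesis == "matched-filter") {
      conv_fir(estimates[k, ], bank$impulse[[k]])
    } else {
      estimates[k, ]
    }
    out <- out + g[k] * ch
  }
  if (cfg$normalize && max(abs(out)) > 0) out <- out / max(abs(out))
  audio_signal(out, bank$fs)
}

#' Reconstruct audio from a waveform-path spike pattern
#'
#' [decode_subbands()] followed by [synthesize()]. The analysis bank slides
#' each FIR forward (a correlation) and the synthesis bank convolves with
#' the time-reversed FIR, so the full chain is delay-free and the output
#' aligns sample-for-sample with the original for metric computation.
#'
#' @param pattern a waveform-path [spike_pattern()].
#' @param bank the analysis [build_filterbank()].
#' @param cfg a [reconstruction_config()].
#' @return An [audio_signal()] of the same duration as the encoded input.
#' @export
reconstruct <- function(pattern, bank, cfg = reconstruction_config()) {
  est <- decode_subbands(pattern, bank, cfg)
  if (ncol(est) == 0L || all(est == 0)) {
    return(audio_signal(numeric(max(1L, ncol(est))) , bank$fs))
  }
  synthesize(est, bank, cfg)
}
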