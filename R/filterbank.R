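#' Constant-Q cochlear filter bank
#'
#' Builds a bank of time-domain FIR cochlear filters. Each filter is a
#' Hann-windowed cosine at its centre frequency, with support length matched
#' to its bandwidth (`M_k = round(alpha * fs / BW_k)`), normalised to unit
#' magnitude gain at the centre frequency. The default preset `"cq20"` ships
#' the canonical 20-filter set used for speech at 20 kHz: 19 constant-Q bands
#' (Q close to 2.87, four bands per octave from about 200 Hz) plus a wide
#' catch-all top band. Synthesis gains are calibrated at build time so that a
#' unit tone at each interior centre frequency survives the
#' analysis-synthesis round trip with unit amplitude.
#'
#' @param K number of filters (ignored when `preset = "cq20"`, which fixes
#'   K = 20).
#' @param f_lo,f_hi frequency range in Hz; `f_hi` must not exceed `fs / 2`.
#' @param fs sampling rate in Hz.
#' @param preset `"cq20"` for the packaged 20-filter table, `"custom"` to
#'   derive filters from `K`, `f_lo`, `f_hi`, or a path to a TSV file with
#'   columns `index`, `centre_hz`, `bandwidth_hz`.
#' @param alpha impulse-response support factor: taps span
#'   `alpha * fs / BW_k` samples.
#' @param q constant Q factor (centre / bandwidth) used for custom banks.
#' @return A `filter_bank` object: per-filter specs (centre, bandwidth, taps),
#'   synthesis gains, sampling rate and frequency range.
#' @examples
#' bank <- build_filterbank(fs = 20000)
#' bank$specs[1, ]    # lowest band: 200.2 Hz centre, 69.3 Hz bandwidth
#' @export
build_filterbank <- function(K = 20, f_lo = 200, f_hi = 8000, fs = 20000,
                             preset = c("cq20", "custom"), alpha = 1.5,
                             q = 2.87) {
  if (is.character(preset) && length(preset) == 1L && file.exists(preset)) {
    tab <- utils::read.delim(preset)
    specs <- data.frame(index = tab$index, centre = tab$centre_hz,
                        bandwidth = tab$bandwidth_hz)
  } else {
    preset <- match.arg(preset)
    if (preset == "cq20") {
      path <- system.file("extdata", "cq20_filters.tsv", package = "spikecodec")
      tab <- utils::read.delim(path)
      specs <- data.frame(index = tab$index, centre = tab$centre_hz,
                          bandwidth = tab$bandwidth_hz)
    } else {
      specs <- derive_bank_specs(K, f_lo, f_hi, q)
    }
  }
  K <- nrow(specs)
  stop_if_not_scalar_number(fs, "fs")
  if (any(specs$centre > fs / 2)) {
    stop("filter centre frequencies must stay below the Nyquist frequency",
         call. = FALSE)
  }
  if (K > 1 && any(diff(specs$centre) <= 0)) {
    stop("centre frequencies must be strictly increasing", call. = FALSE)
  }

  impulse <- vector("list", K)
  for (k in seq_len(K)) {
    impulse[[k]] <- cochlear_fir(specs$centre[k], specs$bandwidth[k], fs, alpha)
  }
  specs$taps <- vapply(impulse, length, integer(1))

  bank <- structure(
    list(specs = specs, impulse = impulse, fs = fs,
         freq_range = c(min(specs$centre), max(specs$centre)),
         synthesis_gains = rep(1, K)),
    class = "filter_bank"
  )
  bank$synthesis_gains <- calibrate_gains(bank)
  bank
}

# Geometrically spaced constant-Q bands plus a wide catch-all top band whose
# lower edge sits at the last constant-Q centre.
derive_bank_specs <- function(K, f_lo, f_hi, q) {
  stop_if_not_scalar_number(K, "K")
  if (K < 1) stop("`K` must be at least 1", call. = FALSE)
  stop_if_not_scalar_number(f_lo, "f_lo")
  stop_if_not_scalar_number(f_hi, "f_hi")
  if (f_lo <= 0 || f_lo > f_hi) {
    stop("need 0 < f_lo <= f_hi", call. = FALSE)
  }
  if (K == 1) {
    centre <- sqrt(f_lo * f_hi)
    return(data.frame(index = 1L, centre = centre, bandwidth = centre / q))
  }
  r <- 2^(1 / 4)  # four bands per octave
  centres <- f_lo * r^(seq_len(K - 1) - 1)
  if (centres[K - 1] >= f_hi) {
    stop("frequency range too narrow for K constant-Q bands", call. = FALSE)
  }
  data.frame(
    index = seq_len(K),
    centre = c(centres, f_hi),
    bandwidth = c(centres / q, 2 * (f_hi - centres[K - 1]))
  )
}

# Hann-windowed cosine at fc, support matched to bandwidth, unit gain at fc.
cochlear_fir <- function(fc, bw, fs, alpha) {
  m <- max(2L, as.integer(round(alpha * fs / bw)))
  n <- seq_len(m) - 1
  win <- 0.5 * (1 - cos(2 * pi * n / (m - 1)))
  taps <- win * cos(2 * pi * fc * n / fs)
  gain <- abs(fir_response(taps, fc, fs))
  taps / gain
}

# Solve per-channel synthesis scalars so a unit tone at each centre frequency
# passes analysis (correlation) + matched synthesis (convolution) + summation
# with unit amplitude. The chain gain of channel j at frequency f is
# |H_j(f)|^2, so we solve A g = 1 with A[i, j] = |H_j(f_i)|^2.
calibrate_gains <- function(bank) {
  K <- nrow(bank$specs)
  A <- matrix(0, K, K)
  for (j in seq_len(K)) {
    A[, j] <- abs(fir_response(bank$impulse[[j]], bank$specs$centre, bank$fs))^2
  }
  g <- tryCatch(solve(A, rep(1, K)), error = function(e) NULL)
  if (is.null(g) || any(!is.finite(g)) || any(g <= 0)) {
    g <- 1 / diag(A)
  }
  g
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf(
    "<filter_bank: %d channels, %.1f-%.1f Hz @ %g Hz>\n",
    nrow(x$specs), x$freq_range[1], x$freq_range[2], x$fs
  ))
  invisible(x)
}

#' Run the analysis filter bank over a signal
#'
#' Decomposes audio into K sub-band waveforms by sliding each cochlear FIR
#' over the signal: channel k output at sample m is the inner product of the
#' taps with the window starting at m, the tail zero-padded, so every channel
#' has the same length as the input.
#'
#' @param x an [audio_signal()].
#' @param bank a [build_filterbank()] result with matching sample rate.
#' @return A K x M numeric matrix of sub-band waveforms (one row per channel).
#' @export
analyze <- function(x, bank) {
  x <- as_audio(x)
  stopifnot(inherits(bank, "filter_bank"))
  if (x$sample_rate != bank$fs) {
    stop(sprintf("sample-rate mismatch: signal %g Hz vs bank %g Hz",
                 x$sample_rate, bank$fs), call. = FALSE)
  }
  K <- nrow(bank$specs)
  out <- matrix(0, K, length(x$samples))
  for (k in seq_len(K)) {
    out[k, ] <- xcorr_fir(x$samples, bank$impulse[[k]])
  }
  rownames(out) <- sprintf("ch%02d", seq_len(K))
  out
}
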