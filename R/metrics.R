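#' Root-mean-square error between two signals
#'
#' `sqrt(mean((x - xhat)^2))` over time-aligned samples.
#'
#' @param x,xhat [audio_signal()]s (or bare numeric vectors) of equal length.
#' @return RMSE in amplitude units.
#' @export
rmse <- function(x, xhat) {
  a <- metric_samples(x); b <- metric_samples(xhat)
  if (length(a) != length(b)) {
    stop("signals must have equal length", call. = FALSE)
  }
  sqrt(mean((a - b)^2))
}

#' Signal-to-distortion ratio in dB
#'
#' `10 * log10(sum(x^2) / sum((x - xhat)^2))`. A silent estimate gives 0 dB
#' when the error energy equals the signal energy (`xhat = 0`); an exact
#' reconstruction is reported as the documented cap of 300 dB rather than
#' +Inf.
#'
#' @param x reference [audio_signal()] (must not be all-zero).
#' @param xhat estimate of the same length.
#' @param cap dB value reported when the error energy is zero.
#' @return SDR in dB.
#' @export
sdr <- function(x, xhat, cap = 300) {
  a <- metric_samples(x); b <- metric_samples(xhat)
  if (length(a) != length(b)) {
    stop("signals must have equal length", call. = FALSE)
  }
  sig <- sum(a^2)
  if (sig == 0) stop("reference signal must not be all-zero", call. = FALSE)
  err <- sum((a - b)^2)
  if (err == 0) return(cap)
  min(10 * log10(sig / err), cap)
}

metric_samples <- function(x) {
  if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
}

#' Spike rate and reduction statistics
#'
#' Compares a processed (e.g. masked) pattern against the raw pattern it was
#' derived from.
#'
#' @param raw,processed [spike_pattern()]s.
#' @return A list: `raw_rate` and `rate` in spikes/second, and
#'   `reduction_pct = 100 * (1 - n_processed / n_raw)`.
#' @export
spike_stats <- function(raw, processed) {
  stopifnot(inherits(raw, "spike_pattern"), inherits(processed, "spike_pattern"))
  n_raw <- nrow(raw$events)
  n_proc <- nrow(processed$events)
  list(
    raw_rate = n_raw / raw$duration,
    rate = n_proc / processed$duration,
    reduction_pct = if (n_raw == 0) 0 else 100 * (1 - n_proc / n_raw)
  )
}

#' External PESQ hook
#'
#' Perceptual speech quality (ITU-T P.862 mapped to MOS-LQO, 1-5) is
#' delegated to an external implementation: supply a function of
#' `(ref_samples, deg_samples, sample_rate)` via the `spikecodec.pesq`
#' option or the `hook` argument. Without a hook the typed marker
#' `"unavailable"` is returned; nothing in the package requires PESQ.
#'
#' @param ref,deg [audio_signal()]s at the same sampling rate.
#' @param hook optional function implementing PESQ.
#' @return MOS-LQO score, or an object of class `pesq_unavailable`.
#' @export
pesq_hook <- function(ref, deg, hook = getOption("spikecodec.pesq")) {
  ref <- as_audio(ref); deg <- as_audio(deg)
  if (ref$sample_rate != deg$sample_rate) {
    stop("sample rates must match for PESQ", call. = FALSE)
  }
  if (!is.function(hook)) {
    return(structure("unavailable", class = "pesq_unavailable"))
  }
  hook(ref$samples, deg$samples, ref$sample_rate)
}

#' Assemble a quality report for a codec run
#'
#' @param ref original [audio_signal()].
#' @param recon reconstructed [audio_signal()] of equal length.
#' @param raw_pattern,processed_pattern the spike patterns before and after
#'   masking (optional; enables spike statistics).
#' @param pesq attempt the external PESQ hook.
#' @return A list of class `quality_report` with `rmse`, `sdr_db`, spike
#'   statistics and provenance labels.
#' @export
quality_report <- function(ref, recon, raw_pattern = NULL,
                           processed_pattern = NULL, pesq = FALSE) {
  out <- list(
    rmse = rmse(ref, recon),
    sdr_db = sdr(ref, recon),
    provenance = c(
      reference = "original",
      estimate = if (!is.null(processed_pattern)) processed_pattern$provenance
                 else "unknown"
    )
  )
  if (!is.null(raw_pattern) && !is.null(processed_pattern)) {
    out <- c(out, spike_stats(raw_pattern, processed_pattern))
  }
  if (pesq) out$pesq_mos <- pesq_hook(ref, recon)
  class(out) <- "quality_report"
  out
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("RMSE: %.4g   SDR: %.2f dB\n", x$rmse, x$sdr_db))
  if (!is.null(x$reduction_pct)) {
    cat(sprintf("Spike rate: %.0f /s (raw %.0f /s), reduction %.2f%%\n",
                x$rate, x$raw_rate, x$reduction_pct))
  }
  if (!is.null(x$pesq_mos)) {
    cat("PESQ (MOS-LQO): ",
        if (inherits(x$pesq_mos, "pesq_unavailable")) "unavailable"
        else sprintf("%.2f", x$pesq_mos), "\n", sep = "")
  }
  invisible(x)
}
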