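# Independent brute-force oracles used to pin down the fast implementations.

# Sliding inner product y[m] = sum_i x[m+i-1] f[i], tail zero-padded:
# literal double loop.
oracle_sliding_product <- function(x, f) {
  m_len <- length(x)
  k_len <- length(f)
  xp <- c(x, numeric(k_len))
  y <- numeric(m_len)
  for (m in seq_len(m_len)) {
    s <- 0
    for (i in seq_len(k_len)) s <- s + xp[m + i - 1] * f[i]
    y[m] <- s
  }
  y
}

# Piecewise-linear level crossings with the arrival-side tie rule:
# scan every segment explicitly.
oracle_crossings <- function(v, t, th, direction) {
  out <- numeric(0)
  for (j in seq_len(length(v) - 1)) {
    a <- v[j]; b <- v[j + 1]
    hit <- if (direction == "up") a < th && b >= th else a > th && b <= th
    if (hit) out <- c(out, t[j] + (th - a) / (b - a) * (t[j + 1] - t[j]))
  }
  out
}

# Simultaneous masking surface: three explicit loops over frames, maskers
# and maskees, then the absolute-threshold floor.
oracle_simultaneous <- function(energies, centres, cfg) {
  K <- nrow(energies); N <- ncol(energies)
  m <- matrix(-Inf, K, N)
  for (j in seq_len(N)) {
    for (ip in seq_len(K)) {
      best <- -Inf
      for (i in seq_len(K)) {
        d <- i - ip
        pen <- cfg$spread_offset +
          if (d > 0) cfg$slope_down * d else cfg$slope_up * (-d)
        best <- max(best, energies[i, j] - pen)
      }
      ta <- absolute_threshold(centres[ip]) - cfg$spl_offset
      m[ip, j] <- max(best, ta)
    }
  }
  m
}

# Frames covering a time instant: every frame whose window contains t.
oracle_covering_frames <- function(t, centres, window_s) {
  which(abs(t - centres) <= window_s / 2 + 1e-12)
}

# Hadamard deletion: keep an event iff any covering frame is audible
# (nearest frame when none covers it).
oracle_mask_keep <- function(events, map, centres, window_s) {
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    cov <- oracle_covering_frames(events$time[i], centres, window_s)
    if (length(cov) == 0L) cov <- which.min(abs(events$time[i] - centres))
    keep[i] <- any(map[events$channel[i], cov] == 1)
  }
  keep
}

# Shared small objects (built once per test file).
default_bank <- function() {
  if (is.null(.test_env$bank)) .test_env$bank <- build_filterbank()
  .test_env$bank
}
.test_env <- new.env(parent = emptyenv())

# A spectrogram-shaped object with prescribed energies, for masking tests
# that need exact toy matrices.
toy_spectrogram <- function(energies, centres = NULL, fs = 20000) {
  K <- nrow(energies)
  if (is.null(centres)) centres <- default_bank()$specs$centre[seq_len(K)]
  framing <- framing_config(fs)
  structure(
    list(energies = energies,
         frame_times = (seq_len(ncol(energies)) - 1) * framing$stride_s +
           (framing$l - 1) / 2 / fs,
         centres = centres, framing = framing, fs = fs,
         duration = ncol(energies) * framing$stride_s + framing$window_s),
    class = "spectrogram"
  )
}
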