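# Internal numeric helpers shared across the codec.

# Sliding inner product of x with FIR taps f: y[m] = sum_i x[m + i - 1] * f[i],
# m = 1..length(x), with the tail zero-padded. FFT-based circular correlation
# with enough padding that no wrap-around occurs.
xcorr_fir <- function(x, f) {
  m_len <- length(x)
  k_len <- length(f)
  n <- stats::nextn(m_len + k_len, factors = 2)
  xf <- stats::fft(c(x, numeric(n - m_len)))
  ff <- stats::fft(c(f, numeric(n - k_len)))
  r <- Re(stats::fft(xf * Conj(ff), inverse = TRUE)) / n
  r[seq_len(m_len)]
}

# Causal full convolution of x with f, truncated to length(x):
# y[n] = sum_j x[j] * f[n - j + 1].
conv_fir <- function(x, f) {
  m_len <- length(x)
  k_len <- length(f)
  n <- stats::nextn(m_len + k_len, factors = 2)
  xf <- stats::fft(c(x, numeric(n - m_len)))
  ff <- stats::fft(c(f, numeric(n - k_len)))
  r <- Re(stats::fft(xf * ff, inverse = TRUE)) / n
  r[seq_len(m_len)]
}

# Complex frequency response of FIR taps f (0-based time indexing) at
# frequencies freq (Hz) for sampling rate fs.
fir_response <- function(f, freq, fs) {
  n <- seq_along(f) - 1
  vapply(freq, function(fq) {
    sum(f * exp(-2i * pi * fq * n / fs))
  }, complex(1))
}

# Evaluate an expression with a locally seeded RNG, restoring global state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(expr)
}

# Grows per-column vectors for spike events without repeated data.frame
# construction; collect() yields the canonical event columns.
event_accumulator <- function() {
  neuron <- list(); time <- list(); channel <- list()
  kind <- list(); level <- list(); amplitude <- list()
  i <- 0L
  add <- function(nrn, t, ch, knd, lvl, amp) {
    if (length(t) == 0L) return(invisible(NULL))
    i <<- i + 1L
    n <- length(t)
    neuron[[i]] <<- rep_len(as.integer(nrn), n)
    time[[i]] <<- t
    channel[[i]] <<- rep_len(as.integer(ch), n)
    kind[[i]] <<- rep_len(knd, n)
    level[[i]] <<- rep_len(as.integer(lvl), n)
    amplitude[[i]] <<- rep_len(as.numeric(amp), n)
    invisible(NULL)
  }
  collect <- function() {
    data.frame(
      neuron = unlist(neuron) %||% integer(),
      time = unlist(time) %||% numeric(),
      channel = unlist(channel) %||% integer(),
      kind = unlist(kind) %||% character(),
      level = unlist(level) %||% integer(),
      amplitude = unlist(amplitude) %||% numeric()
    )
  }
  list(add = add, collect = collect)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
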