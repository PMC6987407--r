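#' Synthetic audio fixture specification
#'
#' Seeded generator specs for the signal classes the codec exercises:
#' `tone` (pure sinusoid), `two_tone_masker` (loud tone plus a nearby quiet
#' tone, a frequency-masking probe), `decaying_bursts` (a loud tone burst
#' followed by quieter bursts at fixed lags, a temporal-masking probe),
#' `chirp` (linear sweep), `noise` (seeded white noise), and `vowel_like`
#' (three damped harmonics of a fundamental under an attack-decay envelope,
#' a stand-in for voiced speech).
#'
#' @param kind one of the six fixture kinds.
#' @param duration_s signal length in seconds.
#' @param sample_rate sampling rate in Hz (default 20 kHz).
#' @param seed integer seed; identical specs generate bit-identical audio.
#' @param ... kind-specific parameters: `freq`, `amp` (tone); `masker_freq`,
#'   `maskee_freq`, `masker_amp`, `maskee_db` (two_tone_masker);
#'   `freq`, `burst_s`, `lags_s`, `maskee_db` (decaying_bursts);
#'   `f0`, `f1` (chirp); `amp` (noise); `f0` (vowel_like).
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("tone", "two_tone_masker", "decaying_bursts",
                                  "chirp", "noise", "vowel_like"),
                         duration_s = 0.5, sample_rate = 20000, seed = 1L,
                         ...) {
  kind <- match.arg(kind)
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  structure(
    c(list(kind = kind, duration_s = duration_s, sample_rate = sample_rate,
           seed = as.integer(seed)), list(...)),
    class = "fixture_spec"
  )
}

#' Generate a synthetic audio fixture
#'
#' Deterministic given the spec (including its seed). All outputs are finite
#' and scaled inside [-1, 1].
#'
#' @param spec a [fixture_spec()].
#' @return An [audio_signal()].
#' @examples
#' x <- generate_fixture(fixture_spec("tone", freq = 1000, amp = 0.5))
#' max(abs(x$samples))  # 0.5
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  fs <- spec$sample_rate
  n <- as.integer(round(spec$duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  p <- function(name, default) if (!is.null(spec[[name]])) spec[[name]] else default
  x <- switch(spec$kind,
    tone = {
      p("amp", 0.5) * sin(2 * pi * p("freq", 1000) * t)
    },
    two_tone_masker = {
      a <- p("masker_amp", 0.5)
      a * sin(2 * pi * p("masker_freq", 952.1) * t) +
        a * 10^(p("maskee_db", -25) / 20) *
          sin(2 * pi * p("maskee_freq", 1131.3) * t)
    },
    decaying_bursts = {
      f <- p("freq", 952.1)
      burst <- p("burst_s", 0.03)
      lags <- p("lags_s", c(0.03, 0.075))
      a <- p("masker_amp", 0.6)
      rel <- 10^(p("maskee_db", -20) / 20)
      y <- numeric(n)
      add_burst <- function(y, t0, amp) {
        i0 <- as.integer(round(t0 * fs)) + 1L
        i1 <- min(n, i0 + as.integer(round(burst * fs)) - 1L)
        if (i0 > n) return(y)
        seg <- i0:i1
        env <- sin(pi * seq_along(seg) / length(seg))^2  # smooth on/off
        y[seg] <- y[seg] + amp * env * sin(2 * pi * f * t[seg])
        y
      }
      y <- add_burst(y, 0.01, a)
      for (lag in lags) y <- add_burst(y, 0.01 + burst + lag, a * rel)
      y
    },
    chirp = {
      f0 <- p("f0", 300); f1 <- p("f1", 4000)
      phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * spec$duration_s))
      p("amp", 0.5) * sin(phase)
    },
    noise = {
      p("amp", 0.3) * with_local_seed(spec$seed, {
        z <- stats::rnorm(n)
        z / max(abs(z))
      })
    },
    vowel_like = {
      f0 <- p("f0", 140)
      formants <- p("formants", c(500, 1500, 2500))
      harmonics <- pmax(1, round(formants / f0))
      amps <- c(1, 0.5, 0.25)
      # syllabic envelope: raised-cosine bumps at roughly 4-5 syllables/s,
      # so frame-energy trajectories re-peak the way running speech does
      n_syll <- p("syllables", max(2L, round(spec$duration_s * 5)))
      syl_len <- spec$duration_s / n_syll
      phase01 <- (t %% syl_len) / syl_len
      weights <- 0.6 + 0.4 * sin(seq_len(n_syll) * 2.1)^2
      env <- sin(pi * phase01)^2 *
        weights[pmin(n_syll, floor(t / syl_len) + 1L)]
      y <- numeric(n)
      for (i in seq_along(harmonics)) {
        y <- y + amps[i] * sin(2 * pi * harmonics[i] * f0 * t)
      }
      y <- y * env
      0.7 * y / max(abs(y))
    }
  )
  peak <- max(abs(x))
  if (peak > 1) x <- x / (peak * 1.02)
  audio_signal(x, fs)
}

#' Canonical fixture suite
#'
#' The 12-item suite every cross-module property runs on: four tones at
#' interior channel centre frequencies, a two-tone simultaneous-masking
#' probe, a decaying-burst temporal-masking probe, a chirp, two noise
#' tokens, and three vowel-like (speech-like) tokens. Regeneration under the
#' same seed is bit-identical.
#'
#' @param seed integer seed for the stochastic members.
#' @return A named list of lists, each with `spec` and `audio`.
#' @export
fixture_suite <- function(seed = 1L) {
  seed <- as.integer(seed)
  specs <- list(
    tone_ch05 = fixture_spec("tone", duration_s = 0.3, freq = 400.4, amp = 0.5),
    tone_ch10 = fixture_spec("tone", duration_s = 0.3, freq = 952.1, amp = 0.5),
    tone_ch15 = fixture_spec("tone", duration_s = 0.3, freq = 2263.7, amp = 0.5),
    tone_ch18 = fixture_spec("tone", duration_s = 0.3, freq = 3805.7, amp = 0.5),
    two_tone = fixture_spec("two_tone_masker", duration_s = 0.4),
    bursts = fixture_spec("decaying_bursts", duration_s = 0.5),
    chirp = fixture_spec("chirp", duration_s = 0.4),
    noise_a = fixture_spec("noise", duration_s = 0.3, seed = seed),
    noise_b = fixture_spec("noise", duration_s = 0.3, seed = seed + 1L),
    vowel_a = fixture_spec("vowel_like", duration_s = 0.4, f0 = 120),
    vowel_b = fixture_spec("vowel_like", duration_s = 0.4, f0 = 160),
    vowel_c = fixture_spec("vowel_like", duration_s = 0.4, f0 = 200)
  )
  lapply(specs, function(s) list(spec = s, audio = generate_fixture(s)))
}
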