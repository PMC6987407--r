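test_that("decoding rejects pattern-path input and handles empties", {
  bank <- default_bank()
  x <- generate_fixture(fixture_spec("tone", freq = 952.1, duration_s = 0.2))
  pp <- threshold_encode(spectrogram(x, bank))
  expect_error(decode_subbands(pp, bank), "level_crossing_encode")
  empty <- spike_pattern(
    data.frame(neuron = integer(), time = numeric(), channel = integer(),
               kind = character(), level = integer(), amplitude = numeric()),
    duration = 0.1, fs = bank$fs, path = "waveform")
  est <- decode_subbands(empty, bank)
  expect_true(all(est == 0))
  y <- reconstruct(empty, bank)
  expect_true(all(y$samples == 0))
})

test_that("decoding interpolates linearly through event amplitudes", {
  bank <- default_bank()
  fs <- bank$fs
  ev <- data.frame(neuron = 0L, time = c(0.01, 0.02, 0.04), channel = 1L,
                   kind = "onset", level = 1:3,
                   amplitude = c(-0.5, 0, 0.5))
  pat <- spike_pattern(ev, duration = 0.05, fs = fs, path = "waveform")
  est <- decode_subbands(pat, bank, reconstruction_config(gap_s = Inf))
  t_axis <- (seq_len(ncol(est)) - 1) / fs
  want <- stats::approx(ev$time, ev$amplitude, xout = t_axis,
                        yleft = 0, yright = 0)$y
  expect_equal(est[1, ], want, tolerance = 1e-12)
  # zero outside the event support
  expect_true(all(est[1, t_axis < 0.01] == 0))
  expect_true(all(est[1, t_axis > 0.04] == 0))
  # other channels silent
  expect_true(all(est[-1, ] == 0))
})

test_that("sine decode matches an independent interpolation oracle", {
  bank <- default_bank()
  fs <- bank$fs
  t <- (0:3999) / fs
  x <- 0.6 * sin(2 * pi * 200 * t)
  pat <- level_crossing_encode(matrix(x, 1), fs = fs, L = 31)
  est <- decode_subbands(pat, bank, reconstruction_config(gap_s = Inf))
  ev <- pat$events[order(pat$events$time), ]
  oracle <- stats::approx(ev$time, ev$amplitude, xout = t,
                          yleft = 0, yright = 0, ties = mean)$y
  expect_equal(est[1, ], oracle, tolerance = 1e-9)
})

test_that("gain calibration passes centre-frequency tones at unit amplitude", {
  # the synthesis gains are solved jointly over the bank, so a tone at an
  # interior centre frequency survives the full analysis-synthesis chain
  # (all channels summed, including neighbour leakage) at unit amplitude
  bank <- default_bank()
  fs <- bank$fs
  t <- (0:19999) / fs
  for (k in c(5, 10, 15)) {
    tone <- audio_signal(sin(2 * pi * bank$specs$centre[k] * t), fs)
    y <- synthesize(analyze(tone, bank), bank)
    mid <- 6000:14000
    amp <- sqrt(2 * mean(y$samples[mid]^2))
    expect_lt(abs(amp - 1), 0.05)
  }
})

test_that("the analysis-synthesis chain has no net group delay", {
  bank <- default_bank()
  fs <- bank$fs
  t <- (0:9999) / fs
  x <- sin(2 * pi * 952.1 * t)
  sub <- analyze(audio_signal(x, fs), bank)
  y <- synthesize(sub, bank)
  mid <- 3000:7000
  lag <- which.max(stats::ccf(y$samples[mid], x[mid], lag.max = 20,
                              plot = FALSE)$acf) - 21
  expect_equal(lag, 0)
})

test_that("round trips preserve tones and silence", {
  bank <- default_bank()
  tone <- generate_fixture(fixture_spec("tone", freq = 1000, amp = 0.5,
                                        duration_s = 1))
  pat <- level_crossing_encode(analyze(tone, bank), bank$fs, L = 31)
  # all-audible masking leaves the pattern intact
  spec <- spectrogram(tone, bank)
  ones <- masking_map(spec, matrix(-Inf, 20, ncol(spec$energies)))
  pat_m <- suppressWarnings(apply_mask(pat, ones, spec))
  expect_equal(n_events(pat_m), n_events(pat))
  y <- reconstruct(pat_m, bank)
  expect_gte(sdr(tone, y), 25)
  # silence round-trips to silence
  sil <- matrix(0, 20, 2000)
  ps <- level_crossing_encode(sil, bank$fs, L = 31)
  expect_equal(n_events(ps), 0L)
  expect_true(all(reconstruct(ps, bank)$samples == 0))
})

test_that("perceptual masking beats random deletion on speech-like audio", {
  bank <- default_bank()
  v <- generate_fixture(fixture_spec("vowel_like", duration_s = 0.4,
                                     f0 = 160))
  sub <- analyze(v, bank)
  spec <- spectrogram(v, bank)
  mk <- compute_masking(spec)
  raw <- level_crossing_encode(sub, bank$fs, L = 31)
  masked <- suppressWarnings(apply_mask(raw, mk$map, spec))
  st <- spike_stats(raw, masked)
  expect_gt(st$reduction_pct, 10)
  rnd <- random_mask_baseline(raw, st$reduction_pct / 100, seed = 101)
  sdr_masked <- sdr(v, reconstruct(masked, bank))
  sdr_random <- sdr(v, reconstruct(rnd, bank))
  expect_gt(sdr_masked, sdr_random)
})
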