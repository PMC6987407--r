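test_that("absolute hearing threshold matches its closed form", {
  # independent evaluation of the three-term approximation
  ta <- function(f) {
    3.64 * (f / 1000)^(-0.8) -
      6.5 * exp(-0.6 * (f / 1000 - 3.3)^2) + 1e-3 * (f / 1000)^4
  }
  expect_equal(absolute_threshold(1000), ta(1000), tolerance = 1e-12)
  expect_equal(absolute_threshold(1000), 3.369067, tolerance = 1e-6)
  expect_equal(absolute_threshold(3300), -4.980885, tolerance = 1e-6)
  expect_equal(absolute_threshold(c(100, 500, 8000)), ta(c(100, 500, 8000)))
  # the sensitivity dip sits at a few kHz
  grid <- seq(20, 16000, by = 1)
  fmin <- grid[which.min(absolute_threshold(grid))]
  expect_gt(fmin, 2000)
  expect_lt(fmin, 5000)
  expect_error(absolute_threshold(0), "positive")
  expect_error(absolute_threshold(-10), "positive")
})

test_that("temporal masking follows the exponential peak-decay scan", {
  sp <- toy_spectrogram(matrix(c(60, 40, 50, 20), nrow = 1))
  thr <- temporal_mask(sp, temporal_mask_config(decay = 0.9))
  expect_equal(as.numeric(thr), c(60, 54, 50, 45))
  # frames 1 and 3 (0-based) fall below threshold
  expect_equal(as.numeric(sp$energies < thr), c(0, 1, 0, 1))
  # direct decay arithmetic: c = 0.5, p1 = 60, two frames later
  sp2 <- toy_spectrogram(matrix(c(60, -100, -100), nrow = 1))
  thr2 <- temporal_mask(sp2, temporal_mask_config(decay = 0.5))
  expect_equal(thr2[1, 3], 0.25 * 60)
  # a peak's own threshold is itself
  expect_equal(thr[1, 1], 60)
  expect_equal(thr[1, 3], 50)
  expect_error(temporal_mask_config(decay = 1.2), "decay")
})

test_that("simultaneous masking matches the exhaustive spreading oracle", {
  cfg <- simultaneous_mask_config()
  set.seed(21)
  e <- matrix(stats::runif(9, -40, 20), 3, 3)
  sp <- toy_spectrogram(e, centres = c(500, 1000, 2000))
  expect_equal(simultaneous_mask(sp, cfg),
               oracle_simultaneous(e, sp$centres, cfg), tolerance = 1e-12)
})

test_that("simultaneous masking spreads a single loud bin triangularly", {
  cfg <- simultaneous_mask_config(spl_offset = 90, spread_offset = 10,
                                  slope_down = 27, slope_up = 15)
  e <- matrix(-100, 5, 3)
  e[3, 2] <- 30
  sp <- toy_spectrogram(e, centres = c(400, 800, 1200, 1600, 2000))
  m <- simultaneous_mask(sp, cfg)
  expect_equal(m[2, 2], 30 - 10 - 27)   # one band toward lower channels
  expect_equal(m[4, 2], 30 - 10 - 15)   # one band toward higher channels
  # silent columns reduce to the absolute-threshold profile
  ta_int <- absolute_threshold(sp$centres) - cfg$spl_offset
  expect_equal(m[, 1], ta_int, tolerance = 1e-9)
})

test_that("combined surface is the bin-wise maximum of its components", {
  set.seed(5)
  a <- matrix(stats::rnorm(16, 0, 20), 4, 4)
  b <- matrix(stats::rnorm(16, 0, 20), 4, 4)
  surf <- combine_masks(a, b)
  expect_true(all(surf$thresholds >= a) && all(surf$thresholds >= b))
  expect_equal(combine_masks(a, matrix(-Inf, 4, 4))$thresholds, a)
  expect_equal(combine_masks(a, a)$thresholds, a)
  expect_error(combine_masks(a, matrix(0, 2, 2)), "dimensions")
})

test_that("the masking map applies the >= audibility rule with ties kept", {
  s <- matrix(c(10, 50, 30, 5), 2, 2, byrow = TRUE)
  m <- matrix(c(20, 20, 30, 30), 2, 2, byrow = TRUE)
  sp <- toy_spectrogram(s, centres = c(500, 1000))
  phi <- masking_map(sp, m)
  expect_equal(unclass(phi)[1:2, 1:2],
               matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  # exact ties survive
  phi_tie <- masking_map(sp, s)
  expect_true(all(phi_tie == 1))
  expect_error(masking_map(sp, matrix(0, 3, 3)), "dimensions")
})

test_that("a louder event never masks itself", {
  bank <- default_bank()
  x <- generate_fixture(fixture_spec("vowel_like", duration_s = 0.3))
  sp <- spectrogram(x, bank)
  mk <- compute_masking(sp)
  i <- 6; j <- which.max(sp$energies[i, ])
  expect_equal(as.numeric(mk$map[i, j]), 1)
  # raising that bin keeps it audible
  sp2 <- sp
  sp2$energies[i, j] <- sp2$energies[i, j] + 30
  mk2 <- compute_masking(sp2)
  expect_equal(as.numeric(mk2$map[i, j]), 1)
})

test_that("disabling spreading and decay reduces to the pure threshold rule", {
  bank <- default_bank()
  x <- generate_fixture(fixture_spec("two_tone_masker", duration_s = 0.3))
  sp <- spectrogram(x, bank)
  sim_cfg <- simultaneous_mask_config(spread_offset = Inf)
  temp_cfg <- temporal_mask_config(decay = 1e-9, scale = "linear")
  mk <- compute_masking(sp, sim_cfg, temp_cfg)
  ta_int <- absolute_threshold(sp$centres) - sim_cfg$spl_offset
  pure <- (sp$energies >= matrix(ta_int, nrow(sp$energies),
                                 ncol(sp$energies))) + 0
  # away from running peaks the map is exactly the absolute-threshold rule;
  # peak bins are audible under both
  expect_true(all(mk$map[pure == 0] %in% c(0, 1)))
  expect_true(all(unclass(mk$map)[, -1][pure[, -1] == 1] == 1))
  mismatch <- mean(unclass(mk$map) != pure)
  expect_lt(mismatch, 0.05)
})

test_that("longer temporal decay masks a non-decreasing fraction of bins", {
  # holds wherever frame energies sit above 0 dB; for sub-zero-dB content
  # the multiplicative decay on the dB value inverts (a shorter decay pushes
  # a negative threshold toward 0, i.e. upward), so the property is checked
  # on fixtures whose active bins are positive-energy
  bank <- default_bank()
  suite <- fixture_suite(seed = 7)
  for (nm in c("vowel_b", "bursts", "two_tone")) {
    sp <- spectrogram(suite[[nm]]$audio, bank)
    frac <- vapply(c(0.5, 0.7, 0.9, 0.95), function(c0) {
      mean(compute_masking(sp, temp_cfg = temporal_mask_config(c0))$map == 0)
    }, numeric(1))
    expect_true(all(diff(frac) >= -1e-12))
  }
})
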