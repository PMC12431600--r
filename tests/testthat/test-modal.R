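test_that("peak detection counts and refines oscillation maxima", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  # phase-shifted cosine: ten interior maxima at t = 0.05, 0.15, ..., 0.95
  tr <- displacement_trace(t, cos(2 * pi * 10 * (t - 0.05)), fs)
  pk <- detect_peaks(tr, interpolate = TRUE)
  expect_length(pk$amplitude, 10)
  expect_equal(pk$amplitude, rep(1, 10), tolerance = 1e-4)
  expect_equal(pk$time, seq(0.05, 0.95, by = 0.1), tolerance = 1e-3)
  # decaying envelope: successive peaks fall by exp(-0.1) per period
  trd <- displacement_trace(t, exp(-t) * cos(2 * pi * 10 * t), fs)
  pkd <- detect_peaks(trd, interpolate = TRUE)
  r <- pkd$amplitude[-1] / pkd$amplitude[-length(pkd$amplitude)]
  expect_equal(r, rep(exp(-0.1), length(r)), tolerance = 1e-3)
  # no oscillation at all
  ramp <- displacement_trace(t, t, fs)
  expect_error(detect_peaks(ramp), "insufficient peaks")
})

test_that("log decrement matches its closed forms", {
  expect_equal(damping_log_decrement(c(2, 2, 2)), 0)
  expect_equal(damping_log_decrement(c(exp(2 * pi), 1), i = 1, j = 1), 1)
  # amplitudes exp(-2 pi 0.394 k) evaluated at a 2-cycle gap
  amps <- exp(-2 * pi * 0.394 * (0:3))
  expect_equal(damping_log_decrement(amps, i = 1, j = 2), 0.394)
  expect_error(damping_log_decrement(c(1, -1)), "positive")
  expect_error(damping_log_decrement(c(1, 0.5), i = 2, j = 1), "range")
})

test_that("estimator agrees with brute-force pairwise evaluation", {
  set.seed(123)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    amps <- exp(rnorm(n))
    j <- sample(1:3, 1)
    if (j >= n) j <- 1
    # aggregate = mean over all valid starting indices at this j
    expected <- mean(sapply(seq_len(n - j), function(i)
      brute_log_decrement(amps, i, j)))
    expect_lt(abs(damping_log_decrement(amps, j = j) - expected), 1e-13)
    i <- sample(n - j, 1)
    expect_lt(abs(damping_log_decrement(amps, i = i, j = j) -
                    brute_log_decrement(amps, i, j)), 1e-13)
  }
})

test_that("estimate is j-invariant on exact exponential peak series", {
  amps <- exp(-2 * pi * 0.25 * (0:7))
  for (j in 1:4) {
    expect_equal(damping_log_decrement(amps, j = j), 0.25, tolerance = 1e-12)
  }
})

test_that("magnitude spectrum locates tones and removes trends", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  tone <- displacement_trace(t, sin(2 * pi * 250 * t), fs)
  sp <- magnitude_spectrum(tone, resolution = 1)
  expect_equal(sp$frequency[which.max(sp$magnitude)], 250)
  expect_equal(sp$resolution, 1)
  # constant trace: detrending leaves nothing
  dc <- displacement_trace(t, rep(3.5, length(t)), fs)
  spd <- magnitude_spectrum(dc, resolution = 1)
  expect_lt(max(spd$magnitude), 1e-6)
  # linearity: a 2x tone has 2x magnitude
  two <- displacement_trace(t, sin(2 * pi * 210 * t) +
                                 2 * sin(2 * pi * 290 * t), fs)
  spt <- magnitude_spectrum(two, resolution = 1)
  m210 <- spt$magnitude[spt$frequency == 210]
  m290 <- spt$magnitude[spt$frequency == 290]
  expect_equal(m290 / m210, 2, tolerance = 1e-3)
  expect_error(magnitude_spectrum(tone, resolution = 0), "positive")
})

test_that("zero-padded grid resolves off-grid tones to half a bin", {
  fs <- 1000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)   # short record, heavy zero-padding
  for (f in c(217.31, 243.97, 271.18)) {
    tr <- displacement_trace(t, cos(2 * pi * f * t), fs)
    sp <- magnitude_spectrum(tr, resolution = 0.05)
    est <- natural_frequency(sp)$natural_frequency
    expect_lt(abs(est - f), 0.05 / 2 + 1e-9)
  }
})

test_that("natural frequency band search, ties and modes behave", {
  sp <- structure(list(frequency = seq(0, 500, by = 1),
                       magnitude = rep(1, 501), resolution = 1),
                  class = "spectrum_mag")
  sp$magnitude[c(241, 261)] <- 10   # equal peaks at 240 and 260 Hz
  expect_equal(natural_frequency(sp)$natural_frequency, 240)
  expect_error(natural_frequency(sp, band = c(600, 700)), "band")
  # first-peak mode returns the lower peak even when a higher one follows
  sp$magnitude[c(241, 261)] <- c(5, 10)
  expect_equal(natural_frequency(sp)$natural_frequency, 260)
  expect_equal(natural_frequency(sp, mode = "first-peak")$natural_frequency,
               240)
})

test_that("feature extraction round-trips all four ripening stages", {
  tab <- stage_parameters()
  for (k in seq_len(nrow(tab))) {
    # frequency path at the camera rate
    gt <- stage_truth(tab$stage[k])
    tr <- generate_displacement(gt, excitation_config(18, 2, 1000))
    feats <- extract_modal_features(tr)
    expect_lt(abs(feats$natural_frequency - tab$frequency_mean[k]), 0.1)
    # damping path on a finely sampled free decay
    trd <- decay_trace(tab$frequency_mean[k], tab$damping_mean[k], fs = 10000)
    fd <- extract_modal_features(trd, band = c(200, 300))
    expect_lt(abs(fd$damping_ratio - tab$damping_mean[k]) /
                tab$damping_mean[k], 0.01)
    expect_gte(fd$n_peaks_used, 2)
  }
})

test_that("features are invariant to trace amplitude scaling", {
  tr <- generate_displacement(stage_truth("ripe"),
                              excitation_config(1, 1, 10000))
  for (c in c(0.01, 5, 1000)) {
    tr2 <- tr; tr2$value <- c * tr$value
    a <- extract_modal_features(tr)
    b <- extract_modal_features(tr2)
    expect_equal(b$damping_ratio, a$damping_ratio, tolerance = 1e-10)
    expect_equal(b$natural_frequency, a$natural_frequency)
  }
})

test_that("undamped traces report zero damping with a warning", {
  tr <- decay_trace(250, 0, fs = 10000, duration = 0.5)
  feats <- extract_modal_features(tr)
  expect_equal(feats$damping_ratio, 0)
})
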