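test_that("noise-free stage sampling reproduces the reference table exactly", {
  tab <- stage_parameters()
  for (k in seq_len(nrow(tab))) {
    gt <- sample_stage_parameters(tab$stage[k], n = 1, sd_scale = 0, seed = k)
    expect_equal(gt$firmness, tab$firmness_mean[k])
    expect_equal(gt$natural_frequency, tab$frequency_mean[k])
    expect_equal(gt$damping_ratio, tab$damping_mean[k])
  }
  expect_error(sample_stage_parameters("rotten", 1), "unknown stage")
})

test_that("stage sampling matches the stated truncated normals (Monte Carlo)", {
  tab <- stage_parameters()
  for (st in c("ripe", "overripe")) {
    row <- tab[tab$stage == st, ]
    gt <- sample_stage_parameters(st, n = 1000, sd_scale = 1, seed = 7)
    # expected means from the closed-form truncated normal; the (0, 1)
    # damping bound shifts the overripe mean visibly below 0.957
    targets <- list(
      c("damping_ratio",
        trunc_norm_mean(row$damping_mean, row$damping_sd, 0, 1)),
      c("natural_frequency",
        trunc_norm_mean(row$frequency_mean, row$frequency_sd, 0)),
      c("firmness", trunc_norm_mean(row$firmness_mean, row$firmness_sd, 0)))
    for (v in targets) {
      x <- gt[[v[1]]]
      se <- sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - as.numeric(v[2])), 3 * se)
    }
  }
  # damping respects its (0, 1) support even when the SD is inflated
  gt <- sample_stage_parameters("overripe", 2000, sd_scale = 5, seed = 8)
  expect_true(all(gt$damping_ratio > 0 & gt$damping_ratio < 1))
  expect_true(all(gt$firmness > 0))
})

test_that("firmness-to-modal map honours the anchors and is monotone", {
  tab <- stage_parameters()
  m <- firmness_to_modal(tab$firmness_mean)
  expect_equal(m$natural_frequency, tab$frequency_mean)
  expect_equal(m$damping_ratio, tab$damping_mean)
  # midpoint of the ripe / semi-ripe anchors interpolates linearly
  mid <- firmness_to_modal((6.56 + 10.37) / 2)
  expect_equal(mid$natural_frequency, (239 + 244) / 2)
  expect_equal(mid$damping_ratio, (0.631 + 0.501) / 2)
  grid <- firmness_to_modal(seq(2.51, 14.41, length.out = 50))
  expect_true(all(diff(grid$natural_frequency) >= 0))
  expect_true(all(diff(grid$damping_ratio) <= 0))
  expect_warning(firmness_to_modal(20), "clamped")
  expect_error(firmness_to_modal(-1), "positive")
})

test_that("simulated decay has the closed-form successive-peak ratio", {
  # log-decrement-consistent envelope: peaks one period apart have ratio
  # exp(2 pi xi) exactly
  tr <- decay_trace(272, 0.394, fs = 10000)
  pk <- detect_peaks(tr, interpolate = TRUE)
  ratios <- pk$amplitude[-length(pk$amplitude)] / pk$amplitude[-1]
  expect_equal(ratios, rep(exp(2 * pi * 0.394), length(ratios)),
               tolerance = 1e-3)
  # zero damping: an undamped cosine with equal peaks
  tr0 <- decay_trace(250, 0, fs = 10000, duration = 0.1)
  pk0 <- detect_peaks(tr0)
  expect_lt(diff(range(pk0$amplitude)), 1e-6)
  # the forced segment alone is a pure sinusoid peaking at f_n
  gt <- stage_truth("semi-ripe")
  trf <- generate_displacement(gt, excitation_config(18, 2, 1000))
  sp <- magnitude_spectrum(trf, resolution = 0.05)
  expect_equal(natural_frequency(sp)$natural_frequency, 244)
})

test_that("physical SDOF convention has the exact-conversion decrement", {
  # peaks are one damped period apart, so the per-cycle decrement is
  # 2 pi xi / sqrt(1 - xi^2); the printed small-damping formula then
  # returns xi / sqrt(1 - xi^2), while the exact conversion returns xi
  f <- 250; xi <- 0.3
  tr <- decay_trace(f, xi, fs = 10000, convention = "physical-sdof")
  pk <- detect_peaks(tr, interpolate = TRUE)
  expect_equal(damping_log_decrement(pk, j = 1), xi / sqrt(1 - xi^2),
               tolerance = 1e-3)
  expect_equal(damping_log_decrement(pk, j = 1, method = "exact-sdof"), xi,
               tolerance = 1e-3)
})

test_that("generation enforces Nyquist and is seed-deterministic", {
  gt <- stage_truth("unripe")
  expect_error(
    generate_displacement(gt, excitation_config(sampling_rate = 500)),
    "Nyquist")
  cfg <- excitation_config(0.2, 0.2, 2000, noise_sd = 0.05, seed = 42)
  a <- generate_displacement(gt, cfg)
  b <- generate_displacement(gt, cfg)
  expect_identical(a$value, b$value)
  cfg2 <- cfg; cfg2$seed <- 43
  expect_false(identical(a$value,
                         generate_displacement(gt, cfg2)$value))
})

test_that("cohorts are stratified, bounded and degenerate without noise", {
  coh <- generate_cohort(120, seed = 3)
  expect_equal(nrow(coh$features), 120)
  expect_equal(unname(table(coh$features$stage)[stage_parameters()$stage]),
               rep(30L, 4), ignore_attr = TRUE)
  fm <- mean(coh$features$natural_frequency_hz)
  expect_gt(fm, 223); expect_lt(fm, 272)
  # zero noise collapses each stage to its mean triple
  coh0 <- generate_cohort(120, sd_scale = 0, seed = 3)
  triples <- unique(coh0$features[, c("damping_ratio",
                                      "natural_frequency_hz",
                                      "firmness_mpa")])
  expect_equal(nrow(triples), 4)
  # stage ordering: frequency falls and damping rises as firmness falls
  ord <- order(-triples$firmness_mpa)
  expect_true(all(diff(triples$natural_frequency_hz[ord]) < 0))
  expect_true(all(diff(triples$damping_ratio[ord]) > 0))
})

test_that("cohort per-stage means track the reference table (Monte Carlo)", {
  coh <- generate_cohort(4000, seed = 11)
  tab <- stage_parameters()
  for (k in seq_len(nrow(tab))) {
    sub <- coh$features[coh$features$stage == tab$stage[k], ]
    mf <- trunc_norm_mean(tab$frequency_mean[k], tab$frequency_sd[k], 0)
    mx <- trunc_norm_mean(tab$damping_mean[k], tab$damping_sd[k], 0, 1)
    se_f <- sd(sub$natural_frequency_hz) / sqrt(nrow(sub))
    se_x <- sd(sub$damping_ratio) / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$natural_frequency_hz) - mf), 3 * se_f)
    expect_lt(abs(mean(sub$damping_ratio) - mx), 3 * se_x)
  }
})
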