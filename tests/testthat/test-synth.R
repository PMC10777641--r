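# Synthetic plant: recruitment, attenuation, gain process, sweep synthesis,
# behavioral generator.

test_that("recruitment is zero at threshold, linear above, and validated", {
  gt <- gt_sham(ecapt_true = 0.038)
  expect_equal(recruitment_amplitude(0.038, gt), 0)
  expect_equal(recruitment_amplitude(0.02, gt), 0)
  # hand arithmetic: 20.53 * (0.082 - 0.038)
  expect_equal(recruitment_amplitude(0.082, gt), 20.53 * 0.044,
               tolerance = 1e-12)
  # linearity: doubling the overdrive doubles the output at fixed gain
  a1 <- recruitment_amplitude(0.038 + 0.01, gt, gain = 1.3)
  a2 <- recruitment_amplitude(0.038 + 0.02, gt, gain = 1.3)
  expect_equal(a2, 2 * a1)
  expect_error(recruitment_amplitude(-0.01, gt), "non-negative")
  expect_error(recruitment_amplitude(0.05, gt, gain = 0), "positive")
})

test_that("distance attenuation is anchored, monotone, and LS-calibrated", {
  gt <- gt_sham()
  expect_equal(distance_attenuation(0.63, 4, gt), 0.63)
  d <- seq(4, 30, by = 0.5)
  att <- distance_attenuation(1, d, gt)
  expect_true(all(diff(att) <= 0))
  expect_error(distance_attenuation(1, 2, gt), ">=")
  # independent oracle: dense grid search over the decay length reproduces
  # the stored least-squares calibration
  ref_d <- c(4, 8, 12, 16); ref_a <- c(0.63, 0.20, 0.09, 0.08)
  grid <- seq(0.5, 20, by = 0.001)
  sse <- vapply(grid, function(l)
    sum((0.63 * exp(-(ref_d - 4) / l) - ref_a)^2), numeric(1))
  expect_equal(gt$decay_length_mm, grid[which.min(sse)], tolerance = 1e-3)
  # the calibrated model tracks the reference profile
  expect_lt(max(abs(distance_attenuation(0.63, ref_d, gt) - ref_a)), 0.062)
})

test_that("gain trace is positive, mean-one, autocorrelated, seeded", {
  expect_equal(gain_trace(10, 50, volatility = 0), rep(1, 500))
  g <- gain_trace(1800, 50, seed = 11)
  expect_length(g, 90000)
  expect_true(all(g > 0))
  expect_lt(abs(mean(g) - 1), 0.02)
  ac <- stats::acf(g, lag.max = 100, plot = FALSE)$acf
  expect_gt(ac[2], ac[101])   # mean reversion
  expect_identical(gain_trace(10, 50, seed = 5), gain_trace(10, 50, seed = 5))
})

test_that("synth_sweep is deterministic and carries its ground truth", {
  gt <- gt_sham()
  r1 <- synth_sweep(gt, seed = 9, program = prog_fixed(0.07))
  r2 <- synth_sweep(gt, seed = 9, program = prog_fixed(0.07))
  expect_identical(r1$sweeps, r2$sweeps)
  tr <- attr(r1, "truth")
  expect_equal(dim(r1$sweeps), c(5, 6, 240))
  # propagation bookkeeping: N1 shift across adjacent contacts = spacing/cv
  expect_equal(diff(rev(tr$n1_latency_ms[1:4])), rep(4 / gt$cv_true, 3))
})

test_that("zero current gives noise-only recording channels", {
  gt <- gt_sham()
  rec <- synth_sweep(gt, seed = 2, program = prog_fixed(0), artifact = FALSE)
  tr <- attr(rec, "truth")
  expect_true(all(tr$amplitude_mv == 0))
  v <- as.numeric(rec$sweeps[, 4, ])
  expect_lt(abs(sd(v) - gt$noise_sd), 0.15 * gt$noise_sd)
  expect_lt(abs(mean(v)), 3 * gt$noise_sd / sqrt(length(v)))
})

test_that("detected N1 shift between contacts matches spacing / cv", {
  gt <- gt_clean()
  rec <- synth_sweep(gt, seed = 1, program = prog_fixed(0.07))
  ft <- feature_table(rec, k = 3)
  f4 <- ft[ft$channel == 4, ]; f3 <- ft[ft$channel == 3, ]
  expect_equal(f3$n1_latency_ms - f4$n1_latency_ms, 4 / gt$cv_true,
               tolerance = 1000 / rec$sample_rate)  # one sample period
})

test_that("sham-calibrated N1 latency falls in the reported band", {
  rec <- synth_sweep(gt_sham(), seed = 4,
                     program = prog_fixed(0.07, n_pulses = 10))
  f <- extract_features(rec, channel = 4, average = TRUE)
  expect_gte(f$n1_latency_ms, 1.373)
  expect_lte(f$n1_latency_ms, 1.433)
})

test_that("a too-slow conduction velocity is rejected for the window", {
  gt <- gt_sham(cv_true = 1.5)  # N1 at 16 mm beyond an 8 ms window
  expect_error(synth_sweep(gt, program = prog_fixed(0.05)), "window")
})

test_that("true recruitment is exactly linear above threshold", {
  gt <- gt_clean()
  currents <- seq(gt$ecapt_true + 0.005, gt$mt_true, length.out = 8)
  amps <- vapply(currents, function(I) {
    rec <- synth_sweep(gt, program = prog_fixed(I, n_pulses = 1))
    attr(rec, "truth")$amplitude_mv[1, 4]
  }, numeric(1))
  fit <- suppressWarnings(summary(lm(amps ~ currents)))  # exact fit
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
  expect_equal(unname(coef(lm(amps ~ currents))[2]), gt$slope,
               tolerance = 1e-9)
})

test_that("behavior generator states the reported BS2 means and domains", {
  cfg <- behavior_effect_config()
  expect_equal(unname(cfg$vf_mean[, "BS2"]),
               c(5.01, 5.11, 5.23, 3.13, 3.48, 3.76))
  tab <- synth_behavior(cfg, n_per_group = 6, seed = 3)
  expect_equal(nrow(tab), 6 * 6 * 7)
  expect_true(all(tab$acetone_latency >= 0))
  expect_true(all(tab$vf_log_threshold <= vf_log_cutoff() + 1e-12))
  expect_identical(tab, synth_behavior(cfg, n_per_group = 6, seed = 3))
  expect_error(synth_behavior(cfg, n_per_group = 1), "n_per_group")
  # per-animal repeated measures: one row per timepoint
  expect_true(all(table(tab$animal_id) == 7))
})
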