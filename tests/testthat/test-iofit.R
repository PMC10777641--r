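# IO recruitment fitting, threshold extrapolation, normalization, ratios.

test_that("an exact line is recovered perfectly", {
  I <- seq(0.035, 0.09, by = 0.005)
  curve <- io_curve(I, 20 * (I - 0.03), mt = 0.09)
  fit <- fit_io(curve)
  expect_equal(fit$slope, 20, tolerance = 1e-6)
  expect_equal(fit$ecapt_extrapolated, 0.03, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("shifting all currents shifts ECAPT and preserves the slope", {
  set.seed(13)
  I <- seq(0.04, 0.09, by = 0.005)
  a <- 20 * (I - 0.03) + rnorm(length(I), 0, 0.02)
  f1 <- fit_io(io_curve(I, a, mt = 0.09))
  f2 <- fit_io(io_curve(I + 0.01, a, mt = 0.10))
  expect_equal(f2$slope, f1$slope, tolerance = 1e-8)
  expect_equal(f2$ecapt_extrapolated, f1$ecapt_extrapolated + 0.01,
               tolerance = 1e-8)
})

test_that("normalization maps ECAPT to 0 and MT to 1 exactly", {
  I <- seq(0.04, 0.082, length.out = 8)
  fit <- fit_io(io_curve(I, 20.5 * (I - 0.038), mt = 0.082))
  expect_equal(normalize_current(fit$ecapt_extrapolated, fit), 0)
  expect_equal(normalize_current(fit$mt, fit), 1)
  expect_true(all(fit$normalized_points$scaled_current <= 1 + 1e-9))
})

test_that("degenerate and inconsistent fits are flagged", {
  I <- seq(0.01, 0.08, length.out = 8)
  expect_error(fit_io(io_curve(I, rev(I) * 10, mt = 0.09)),
               "degenerate")
  # positive slope but x-intercept beyond MT
  I2 <- seq(0.005, 0.02, length.out = 6)
  expect_warning(fit_io(io_curve(I2, 0.001 * (I2 - 0.021), mt = 0.02)),
                 "inconsistent")
  expect_error(io_curve(c(0.01, 0.02), c(0, 0.1), mt = 0.05), "3 points")
  expect_error(io_curve(c(0.03, 0.02, 0.04), c(1, 2, 3), mt = 0.05),
               "increasing")
  expect_error(io_curve(c(0.02, 0.03, 0.06), c(1, 2, 3), mt = 0.05),
               "<= mt")
})

test_that("observed ECAPT finds the first detectable step", {
  gt <- gt_clean(ecapt_true = 0.024, mt_true = 0.049)
  currents <- seq(0, 0.049, by = 0.001)
  res <- synth_io_curve(gt, currents_ma = currents, n_pulses = 3)
  expect_lte(res$observed_ecapt, 0.026)
  expect_gt(res$observed_ecapt, 0.024 - 1e-12)
})

test_that("all-noise staircases signal not-found", {
  gt <- gt_sham()
  feats <- do.call(rbind, lapply(1:4, function(s) {
    rec <- synth_sweep(gt, seed = s, program = prog_fixed(0, n_pulses = 6),
                       artifact = FALSE)
    extract_features(rec, 4, average = TRUE)
  }))
  expect_warning(res <- observed_ecapt(seq(0.01, 0.04, by = 0.01), feats),
                 "no detectable")
  expect_true(is.na(res))
})

test_that("observed and extrapolated ECAPT agree on low-noise fixtures", {
  step <- 0.002
  gt <- gt_sham(noise_sd = 0.003, gain_volatility = 0.02)
  res <- synth_io_curve(gt, currents_ma = seq(0, gt$mt_true, by = step),
                        n_pulses = 6, seed = 31)
  fit <- fit_io(res$curve)
  expect_lte(abs(res$observed_ecapt - fit$ecapt_extrapolated), 2 * step)
})

test_that("MT:ECAPT ratio behaves", {
  expect_equal(mt_ecapt_ratio(0.05, 0.05), 1)
  expect_equal(mt_ecapt_ratio(0.082, 0.038), 2.158, tolerance = 5e-4)
  expect_error(mt_ecapt_ratio(0.05, 0), "undefined")
})

test_that("stimulus intensities reproduce the worked example", {
  s <- stimulus_intensity(0.034, ecapt = 0.024, mt = 0.049)
  expect_equal(round(s$percent_of_mt), 69)
  expect_equal(round(s$times_ecapt, 1), 1.4)
})

test_that("slope and threshold are recovered across a noisy cohort", {
  n_curves <- 30
  gt <- gt_sham()
  res <- lapply(seq_len(n_curves), function(s)
    synth_io_curve(gt, seed = 100 + s))
  fits <- lapply(res, function(r) fit_io(r$curve))
  slope_err <- vapply(fits, function(f)
    abs(f$slope - gt$slope) / gt$slope, numeric(1))
  ecapt_err <- vapply(fits, function(f)
    abs(f$ecapt_extrapolated - gt$ecapt_true) / gt$ecapt_true, numeric(1))
  expect_lt(median(slope_err), 0.05)
  expect_lt(median(ecapt_err), 0.10)
  ratios <- vapply(fits, function(f)
    mt_ecapt_ratio(gt$mt_true, f$ecapt_extrapolated), numeric(1))
  expect_true(all(ratios > 1))
})
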