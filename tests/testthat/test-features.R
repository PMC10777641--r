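# Triphasic feature extraction and detectability.

test_that("landmarks are recovered within one sample of generator truth", {
  gt <- gt_clean()
  rec <- synth_sweep(gt, program = prog_fixed(0.07))
  tr <- attr(rec, "truth")
  dt <- 1000 / rec$sample_rate
  for (ch in c(3, 4)) {
    f <- extract_features(rec, channel = ch)
    expect_true(all(abs(f$n1_latency_ms - tr$n1_latency_ms[ch]) <= dt))
    expect_true(all(f$p1_latency_ms < f$n1_latency_ms))
    expect_true(all(f$n1_latency_ms < f$p2_latency_ms))
    # amplitude equals |P2 - N1| and matches the injected amplitude
    expect_equal(f$amplitude, abs(f$p2_value - f$n1_value))
    expect_equal(f$amplitude, tr$amplitude_mv[, ch], tolerance = 0.02)
  }
})

test_that("latencies are translation-equivariant", {
  set.seed(21)
  n <- 400
  t_ms <- (seq_len(n) - 1) / 30
  wave <- -exp(-(t_ms - 2)^2 / 0.05) + 0.5 * exp(-(t_ms - 2.5)^2 / 0.05) +
    0.3 * exp(-(t_ms - 1.5)^2 / 0.05) + rnorm(n, 0, 0.01)
  shift <- 15L
  m <- rbind(wave, c(rep(0, shift), wave[seq_len(n - shift)]))
  rec <- recording_from_matrix(m)
  f <- extract_features(rec, channel = 1, search_window_ms = c(0.5, 8))
  dt <- 1000 / rec$sample_rate
  expect_equal(f$n1_latency_ms[2] - f$n1_latency_ms[1], shift * dt)
  expect_equal(f$p1_latency_ms[2] - f$p1_latency_ms[1], shift * dt)
  expect_equal(f$p2_latency_ms[2] - f$p2_latency_ms[1], shift * dt)
})

test_that("amplitude is never negative, also under polarity flips", {
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(rnorm(300, 0, 0.05), 1)
    f1 <- extract_features(recording_from_matrix(m), 1,
                           search_window_ms = c(0.5, 8))
    f2 <- extract_features(recording_from_matrix(-m), 1,
                           search_window_ms = c(0.5, 8))
    expect_gte(f1$amplitude, 0)
    expect_gte(f2$amplitude, 0)
  }
})

test_that("extracted amplitude is non-decreasing in current (noiseless)", {
  gt <- gt_clean()
  currents <- seq(0, gt$mt_true, length.out = 10)
  amps <- vapply(currents, function(I) {
    rec <- synth_sweep(gt, program = prog_fixed(I, n_pulses = 1))
    extract_features(rec, channel = 4)$amplitude
  }, numeric(1))
  expect_true(all(diff(amps) >= -1e-12))
})

test_that("pure-noise recordings are not flagged as detectable", {
  gt <- gt_sham()
  for (s in 1:5) {
    rec <- synth_sweep(gt, seed = s, program = prog_fixed(0, n_pulses = 10),
                       artifact = FALSE)
    f <- extract_features(rec, channel = 4, average = TRUE)
    expect_false(is_detectable(f))
  }
})

test_that("detectability rule follows amplitude, noise floor and ordering", {
  base <- data.frame(p1_latency_ms = 1.2, n1_latency_ms = 1.4,
                     p2_latency_ms = 1.7, amplitude = 0.5,
                     noise_sd = 0.05, n_averaged = 1L)
  expect_true(is_detectable(base))           # 10x noise, ordered
  expect_false(is_detectable(transform(base, amplitude = 0)))
  expect_false(is_detectable(transform(base, amplitude = 0.1)))  # 2x noise
  disordered <- transform(base, p1_latency_ms = 1.5)
  expect_false(is_detectable(disordered))
  expect_error(is_detectable(transform(base, noise_sd = NA)), "noise_sd")
})

test_that("below-threshold noiseless sweeps are not detectable", {
  gt <- gt_clean(ecapt_true = 0.038)
  rec <- synth_sweep(gt, program = prog_fixed(0.037, n_pulses = 3))
  f <- extract_features(rec, channel = 4, average = TRUE)
  expect_false(is_detectable(f))
})

test_that("invalid extraction requests are rejected", {
  rec <- synth_sweep(gt_clean(), program = prog_fixed(0.07))
  expect_error(extract_features(rec, channel = rec$geometry$stim_index),
               "stimulation channel")
  expect_error(extract_features(rec, 4, search_window_ms = c(0.5, 50)),
               "beyond the sweep")
  expect_error(extract_features(rec, 4, search_window_ms = c(4.9, 5)),
               "shorter")
})

test_that("flat traces yield amplitude 0 and no detection", {
  m <- matrix(0, 2, 300)
  f <- extract_features(recording_from_matrix(m), 1,
                        search_window_ms = c(0.5, 8))
  expect_equal(f$amplitude, c(0, 0))
  expect_false(is_detectable(f[1, ]))
})
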