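# Closed-loop simulation: controller, sessions, summaries.

test_that("controller update is integral, capped and clamped", {
  p <- list(gain_i = 0.02, step_cap = 0.005, cap = 0.08)
  expect_equal(controller_update(0, 0.04, p), 0.04)
  expect_equal(controller_update(10, 0.04, p), 0.045)   # step cap
  expect_equal(controller_update(-10, 0.04, p), 0.035)
  expect_equal(controller_update(-10, 0.002, p), 0)     # lower clamp
  expect_equal(controller_update(10, 0.079, p), 0.08)   # upper clamp
  expect_error(controller_update(NaN, 0.04, p), "finite")
})

test_that("the loop converges geometrically on a constant plant", {
  # linear recurrence oracle: e_{n+1} = (1 - gain_i * slope) * e_n
  slope <- 20; ecapt <- 0.03; target <- 0.3
  p <- list(gain_i = 0.02, step_cap = 1, cap = 1)
  I <- 0.05; fixed <- ecapt + target / slope
  errs <- numeric(20)
  for (n in 1:20) {
    a <- slope * max(I - ecapt, 0)
    errs[n] <- abs(I - fixed)
    I <- controller_update(target - a, I, p)
  }
  rho <- abs(1 - p$gain_i * slope)
  expect_equal(errs[6:15] / errs[5:14], rep(rho, 10), tolerance = 1e-9)
})

test_that("noise-free CL converges to the fixed point of the loop", {
  gt <- gt_clean()
  prog <- stimulus_program(50, 200, duration_s = 20, current_ma = 0)
  log <- run_session("CL", gt, prog, target_mv = 0.3, amp_noise_sd = 0)
  n <- nrow(log)
  expect_equal(log$current_ma[n], gt$ecapt_true + 0.3 / gt$slope,
               tolerance = 1e-9)
  expect_equal(log$amplitude_mv[n], 0.3, tolerance = 1e-7)
})

test_that("a 30-min 50 Hz session performs one update per pulse", {
  gt <- gt_animal2()
  prog <- stimulus_program(50, 200, duration_s = 1800, current_ma = 0)
  log <- run_session("CL", gt, prog, target_mv = 0.1495, seed = 2)
  expect_equal(nrow(log), 90000)
  expect_equal(attr(log, "n_updates"), 90000L)
  expect_equal(attr(log, "n_updates") / 1800, 50)
  ol <- run_session("OL", gt, prog, target_mv = 0.1495, seed = 2)
  expect_equal(length(unique(ol$current_ma)), 1L)  # OL holds current
})

test_that("currents respect the safety clamp under wild disturbances", {
  gt <- gt_animal2(gain_volatility = 1, gain_tau_s = 0.2)
  prog <- stimulus_program(50, 200, duration_s = 30, current_ma = 0)
  log <- run_session("CL", gt, prog, target_mv = 0.3, seed = 5,
                     amp_noise_sd = 0.2,
                     controller = list(cap = 0.05, step_cap = 0.02))
  expect_true(all(log$current_ma >= 0))
  expect_true(all(log$current_ma <= 0.05 + 1e-12))
})

test_that("unreachable targets raise the saturation flag", {
  gt <- gt_animal2()
  prog <- stimulus_program(50, 200, duration_s = 1, current_ma = 0)
  log <- run_session("CL", gt, prog, target_mv = 0.3, seed = 1,
                     controller = list(cap = 0.02))
  expect_true(attr(log, "saturated"))
  expect_error(run_session("CL", gt, prog, target_mv = 10), "target_mv")
})

test_that("CL reduces amplitude variability against paired OL runs", {
  gt <- gt_animal2()
  prog <- stimulus_program(50, 200, duration_s = 120, current_ma = 0)
  for (s in 1:5) {
    cl <- summarize_session(run_session("CL", gt, prog, 0.1495, seed = s))
    ol <- summarize_session(run_session("OL", gt, prog, 0.1495, seed = s))
    expect_lt(cl$sd_amplitude / cl$mean_amplitude,
              ol$sd_amplitude / ol$mean_amplitude)
  }
})

test_that("session summary applies the single-pass 3-SD rule exactly", {
  # constant amplitude: nothing excluded, SD zero
  log <- data.frame(time_s = 0:99 / 50, current_ma = 0.03,
                    amplitude_mv = 0.25)
  s <- summarize_session(log)
  expect_equal(s$sd_amplitude, 0)
  expect_equal(s$n_excluded, 0)
  # bounded clean values plus 10 far spikes: exactly the spikes go
  set.seed(7)
  n <- 10000
  amp <- runif(n, 0.24, 0.26)
  spike_at <- sample(n, 10)
  amp[spike_at] <- 0.25 + 10 * sd(amp)
  log2 <- data.frame(time_s = seq_len(n) / 50, current_ma = 0.03,
                     amplitude_mv = amp)
  s2 <- summarize_session(log2)
  expect_equal(s2$n_excluded, 10)
  expect_equal(s2$n_included, n - 10)
  expect_lt(max(abs(s2$mean_amplitude - 0.25)), 0.001)
  # histograms integrate to the included count
  log3 <- run_session("CL", gt_animal2(), stimulus_program(50, 200, 60, 0),
                      0.1495, seed = 9)
  s3 <- summarize_session(log3)
  expect_equal(sum(s3$amplitude_error_hist$count), s3$n_included)
  expect_equal(sum(s3$current_minus_ecapt_hist$count), s3$n_included)
})

test_that("the animal-2 replication fixture hits its amplitude target", {
  gt <- gt_animal2()
  prog <- stimulus_program(50, 200, duration_s = 1800, current_ma = 0)
  log <- run_session("CL", gt, prog, target_mv = 0.1495, seed = 12)
  s <- summarize_session(log)
  expect_lt(abs(s$mean_amplitude - 0.1495) / 0.1495, 0.01)
  expect_gt(s$percent_of_mt, 10)   # inside the ECAPT-MT window
  expect_lt(s$percent_of_mt, 60)
})
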