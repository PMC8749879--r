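# Event detection against simulator ground truth, and trial aggregation.

test_that("a constant 1 g trace contains no jumps", {
  tr <- accel_trace(rep(1, 500), fs_hz = 100)
  ev <- detect_jump_events(tr)
  expect_s3_class(ev, "jump_events")
  expect_equal(nrow(ev), 0L)
})

test_that("a single noiseless jump is recovered within one sample", {
  sim <- simulate_jump_trace(list(jump_spec(0.25, 0.50)), fs_hz = 100,
                             noise_sd_g = 0, seed = 1)
  ev <- detect_jump_events(sim$trace)
  expect_equal(nrow(ev), 1L)
  expect_lte(abs(ev$tc_s - 0.25), 0.01)
  expect_lte(abs(ev$tf_s - 0.50), 0.01)
})

test_that("a 15-jump noiseless trial is recovered jump by jump", {
  set.seed(42)
  jumps <- lapply(seq_len(15), function(i)
    jump_spec(stats::runif(1, 0.15, 0.6), stats::runif(1, 0.3, 0.8)))
  sim <- simulate_jump_trace(jumps, fs_hz = 100, noise_sd_g = 0, seed = 3)
  ev <- detect_jump_events(sim$trace)
  expect_equal(nrow(ev), 15L)
  # within one sample of the realized grid boundaries, and of the spec
  expect_lte(max(abs(ev$tc_s - sim$events$tc_s)), 1 / 100 + 1e-12)
  expect_lte(max(abs(ev$tf_s - sim$events$tf_s)), 1e-12)
  expect_lte(max(abs(ev$tc_s - sim$events$tc_spec_s)), 1 / 100 + 1e-12)
  expect_lte(max(abs(ev$tf_s - sim$events$tf_spec_s)), 1 / 100 + 1e-12)
})

test_that("detection survives realistic sensor noise", {
  set.seed(7)
  jumps <- lapply(seq_len(10), function(i)
    jump_spec(stats::runif(1, 0.2, 0.5), stats::runif(1, 0.35, 0.7)))
  sim <- simulate_jump_trace(jumps, fs_hz = 100, noise_sd_g = 0.03, seed = 9)
  ev <- detect_jump_events(sim$trace)
  expect_equal(nrow(ev), 10L)
  expect_lte(max(abs(ev$tf_s - sim$events$tf_s)), 0.02 + 1e-12)
  expect_lte(max(abs(ev$tc_s - sim$events$tc_s)), 0.03 + 1e-12)
})

test_that("detected events are invariant to the trace start time", {
  sim <- simulate_jump_trace(list(jump_spec(0.3, 0.5), jump_spec(0.28, 0.45)),
                             fs_hz = 200, noise_sd_g = 0, seed = 1)
  ev0 <- detect_jump_events(sim$trace)
  shifted <- accel_trace(sim$trace$samples, sim$trace$fs_hz, t0 = 123.4)
  ev1 <- detect_jump_events(shifted)
  expect_equal(ev1$tc_s, ev0$tc_s)
  expect_equal(ev1$tf_s, ev0$tf_s)
  expect_equal(ev1$takeoff_s, ev0$takeoff_s + 123.4)
})

test_that("detect -> resynthesize -> detect is idempotent within a sample", {
  set.seed(11)
  jumps <- lapply(seq_len(8), function(i)
    jump_spec(stats::runif(1, 0.2, 0.5), stats::runif(1, 0.35, 0.7)))
  sim <- simulate_jump_trace(jumps, fs_hz = 100, noise_sd_g = 0.02, seed = 5)
  ev1 <- detect_jump_events(sim$trace)
  clean <- simulate_jump_trace(
    lapply(seq_len(nrow(ev1)), function(i) jump_spec(ev1$tc_s[i], ev1$tf_s[i])),
    fs_hz = 100, noise_sd_g = 0, seed = 1)
  ev2 <- detect_jump_events(clean$trace)
  expect_equal(nrow(ev2), nrow(ev1))
  expect_lte(max(abs(ev2$tc_s - ev1$tc_s)), 0.01 + 1e-12)
  expect_lte(max(abs(ev2$tf_s - ev1$tf_s)), 0.01 + 1e-12)
})

test_that("bosco_summary aggregates and filters correctly", {
  body <- body_params(72.4)
  one <- data.frame(tc_s = 0.25, tf_s = 0.5)
  bs1 <- bosco_summary(one, body)
  expect_equal(bs1$h_max_m, flight_height(0.5))
  expect_equal(bs1$mean_power_w, mean_power(body, 0.25, 0.5))
  expect_equal(bs1$stiffness_nm, leg_stiffness(body, 0.25, 0.5))
  expect_equal(bs1$n_jumps, 1L)

  ten <- one[rep(1, 10), ]
  bs10 <- bosco_summary(ten, body)
  expect_equal(bs10$n_jumps, 10L)
  expect_equal(bs10$mean_power_w, bs1$mean_power_w)

  # internal consistency of the aggregate: h = g tf^2 / 8
  expect_equal(bs10$h_max_m, 9.81 * bs10$tf_s^2 / 8)

  with_outlier <- rbind(ten, data.frame(tc_s = 0.25, tf_s = 1.5))
  bs_f <- bosco_summary(with_outlier, body)
  expect_equal(bs_f$n_jumps, 10L)
  expect_equal(bs_f$tf_s, 0.5)

  all_bad <- data.frame(tc_s = c(0.02, 0.03), tf_s = c(0.5, 0.5))
  expect_error(bosco_summary(all_bad, body), "contact-time")
  expect_error(bosco_summary(one[0, ], body), "no jump events")
})
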