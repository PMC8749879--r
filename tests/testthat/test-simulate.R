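# Synthetic-data generator: physical levels, determinism, study geometry
# and the configured downfall/recovery trajectory.

test_that("trace construction matches its physical specification", {
  sim <- simulate_jump_trace(list(jump_spec(0.25, 0.50)), fs_hz = 100,
                             noise_sd_g = 0, lead_s = 2, seed = 1)
  x <- sim$trace$samples
  ev <- sim$events
  flight <- x[ev$takeoff_idx:(ev$landing_idx - 1)]
  expect_equal(length(flight), 50L)             # 0.5 s at 100 Hz
  expect_true(all(flight == 0))                 # ideal free fall
  standing <- x[1:(ev$contact_start_idx - 1)]
  expect_true(all(standing == 1))               # quiet standing at 1 g
  contact <- x[ev$contact_start_idx:(ev$takeoff_idx - 1)]
  expect_true(all(contact > 1))
  expect_lte(max(contact), 2.5)                 # peak_contact_gain
})

test_that("simulator rejects degenerate inputs", {
  expect_error(simulate_jump_trace(list(), 100), "empty")
  expect_error(simulate_jump_trace(list(jump_spec(0.3, 0.02)), fs_hz = 100),
               "fewer than 3 samples")
  expect_error(simulate_jump_trace(list(jump_spec(0.3, 0.5)), fs_hz = 20),
               "fs_hz")
  expect_error(jump_spec(0.3, 0.5, peak_contact_gain = 0.9),
               "peak_contact_gain")
})

test_that("noisy standing level averages to 1 g", {
  sim <- simulate_jump_trace(list(jump_spec(0.25, 0.5)), fs_hz = 100,
                             noise_sd_g = 0.02, lead_s = 5, seed = 42)
  standing <- sim$trace$samples[1:(sim$events$contact_start_idx[1] - 1)]
  expect_lt(abs(mean(standing) - 1), 3 * 0.02 / sqrt(length(standing)))
})

test_that("simulation is deterministic in the seed and sensitive to it", {
  a <- simulate_jump_trace(list(jump_spec(0.3, 0.5)), 100, 0.02, seed = 5)
  b <- simulate_jump_trace(list(jump_spec(0.3, 0.5)), 100, 0.02, seed = 5)
  c <- simulate_jump_trace(list(jump_spec(0.3, 0.5)), 100, 0.02, seed = 6)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_false(identical(a$trace$samples, c$trace$samples))

  d1 <- simulate_cohort(seed = 3)
  d2 <- simulate_cohort(seed = 3)
  d3 <- simulate_cohort(seed = 4)
  expect_identical(d1$parameters, d2$parameters)
  expect_false(identical(d1$parameters$value, d3$parameters$value))
})

test_that("session scalars follow the configured construction", {
  cfg <- noiseless_config()
  ds <- simulate_cohort(cfg, seed = 1)
  ath <- as.list(ds$athletes[1, ])
  rec <- simulate_session(ath, week = 2, cfg, seed = 10)
  sc <- rec$scalars
  depth <- cfg$subgroup_offsets$fatigue_depth[[ath$training_group]]
  expect_equal(sc$wingate_mean_power_post,
               sc$wingate_mean_power_pre *
                 (1 - (1 - cfg$wingate_effect_by_week[2]) * depth))
  expect_equal(sc$hr_mean, cfg$hr_weekly_bpm[2] +
                 cfg$subgroup_offsets$hr_bpm[[ath$training_group]])
  expect_equal(sc$distance_m, prescribed_distance(cfg))
  # identical seed, identical record
  rec2 <- simulate_session(ath, week = 2, cfg, seed = 10)
  expect_identical(rec$scalars, rec2$scalars)
  expect_error(simulate_session(ath, week = 9, cfg, seed = 1), "outside")
})

test_that("HR series length matches a 45-min session at 5-s sampling", {
  cfg <- cohort_config()
  ds <- simulate_cohort(cfg, seed = 1)
  rec <- simulate_session(as.list(ds$athletes[1, ]), 1, cfg, seed = 2,
                          include_traces = TRUE)
  expect_equal(length(rec$traces$hr$bpm), 45 * 60 / 5)  # 540
  expect_equal(rec$traces$hr$sample_period_s, 5)
})

test_that("default study design: 8 athletes, (2,2,1,1) sessions per week", {
  ds <- simulate_cohort(seed = 2)
  expect_equal(nrow(ds$athletes), 8L)
  expect_equal(length(ds$sessions), 8L * (2L + 2L + 1L + 1L))
  weeks <- vapply(ds$sessions, `[[`, integer(1), "week")
  expect_equal(as.vector(table(weeks)) / 8L, c(2, 2, 1, 1))
})

test_that("noiseless post/pre ratios equal the configured fatigue effects", {
  cfg <- noiseless_config()
  ds <- simulate_cohort(cfg, seed = 1)
  p <- ds$parameters
  for (w in 1:4) {
    pw <- p[p$week == w & p$parameter == "wingate_mean_power", ]
    ratio <- pw$value[pw$phase == "post"] / pw$value[pw$phase == "pre"]
    grp <- ds$athletes$training_group[match(
      pw$athlete_id[pw$phase == "post"], ds$athletes$athlete_id)]
    depth <- unname(unlist(cfg$subgroup_offsets$fatigue_depth[grp]))
    want <- 1 - (1 - cfg$wingate_effect_by_week[w]) * depth
    expect_equal(ratio, want, tolerance = 1e-12)
    # bosco flight time scales by the bosco effect
    bw <- p[p$week == w & p$parameter == "bosco_tf", ]
    bratio <- bw$value[bw$phase == "post"] / bw$value[bw$phase == "pre"]
    bwant <- 1 - (1 - cfg$bosco_effect_by_week[w]) * depth
    expect_equal(bratio, bwant, tolerance = 1e-12)
  }
})

test_that("noiseless trajectory bottoms out at the nadir week then recovers", {
  cfg <- noiseless_config()
  ds <- simulate_cohort(cfg, seed = 1)
  p <- ds$parameters[ds$parameters$parameter == "wingate_mean_power", ]
  ratios <- vapply(1:4, function(w) {
    pw <- p[p$week == w, ]
    stats::median(pw$value[pw$phase == "post"] / pw$value[pw$phase == "pre"])
  }, numeric(1))
  expect_equal(which.min(ratios), cfg$nadir_week)
  after <- ratios[cfg$nadir_week:4]
  expect_true(all(diff(after) > 0))
})

test_that("shuttle geometry is identical across weeks when noiseless", {
  cfg <- noiseless_config()
  ds <- simulate_cohort(cfg, seed = 1)
  ath <- as.list(ds$athletes[1, ])
  d <- vapply(1:4, function(w) {
    rec <- simulate_session(ath, w, cfg, seed = 100 + w,
                            include_traces = TRUE)
    total_distance(rec$traces$gnss)
  }, numeric(1))
  expect_lt(max(d) - min(d), 1e-6)
  expect_equal(d[1], prescribed_distance(cfg), tolerance = 1e-3)
})

test_that("config validation enforces the study invariants", {
  expect_error(cohort_config(nadir_week = 7), "nadir_week")
  expect_error(cohort_config(sessions_per_week = c(2, 2, 1)), "one entry")
  expect_error(cohort_config(wingate_effect_by_week = c(0.9, 1.2, 0.95, 1)),
               "\\(0, 1\\]")
  expect_error(cohort_config(wingate_effect_by_week = c(0.8, 0.9, 0.85, 1)),
               "nadir")
  expect_error(cohort_config(noise_cv = -1), "noise_cv")
  # constant (null) trajectories are legitimate
  expect_s3_class(null_config(), "cohort_config")
})
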