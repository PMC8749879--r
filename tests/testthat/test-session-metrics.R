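# Session-level metrics: heart rate averaging, haversine distances,
# Wingate powers.

test_that("mean heart rate averages non-missing 5-s estimates", {
  expect_equal(mean_heart_rate(hr_series(150)), 150)
  expect_equal(mean_heart_rate(hr_series(c(140, 150, 160))), 150)
  expect_equal(mean_heart_rate(hr_series(c(140, NA, 160))), 150)
  expect_error(mean_heart_rate(hr_series(c(NA_real_, NA_real_))), "missing")
  expect_error(hr_series(c(150, 400)), "bpm")
})

test_that("total distance follows spherical geometry (R = 6371 km)", {
  same <- gnss_track(c(0, 10), c(43.7, 43.7), c(11.3, 11.3))
  expect_equal(total_distance(same), 0)
  # one degree of latitude at constant longitude
  deg <- gnss_track(c(0, 1000), c(43, 44), c(11, 11))
  expect_equal(total_distance(deg), 6371000 * pi / 180, tolerance = 1e-6)
  expect_error(total_distance(gnss_track(0, 43, 11)), "two track points")
})

test_that("distance is additive over concatenation and time-shift invariant", {
  set.seed(1)
  lat <- 43 + cumsum(stats::runif(6, 0, 1e-4))
  lon <- 11 + cumsum(stats::runif(6, 0, 1e-4))
  t <- seq_len(6)
  whole <- gnss_track(t, lat, lon)
  first <- gnss_track(t[1:3], lat[1:3], lon[1:3])
  second <- gnss_track(t[3:6], lat[3:6], lon[3:6])
  expect_equal(total_distance(whole),
               total_distance(first) + total_distance(second))
  shifted <- gnss_track(t + 500, lat, lon)
  expect_equal(total_distance(shifted), total_distance(whole))
})

test_that("simulated noiseless shuttle track has the prescribed length", {
  cfg <- noiseless_config()
  ds <- simulate_cohort(cfg, seed = 1)
  rec <- simulate_session(as.list(ds$athletes[1, ]), 1, cfg, seed = 3,
                          include_traces = TRUE)
  d <- total_distance(rec$traces$gnss)
  expect_lt(abs(d - prescribed_distance(cfg)) / prescribed_distance(cfg),
            0.001)
})

test_that("wingate powers: mean, windowed peak, and their ordering", {
  const <- wingate_trial(rep(400, 300), fs_hz = 10)
  wp <- wingate_powers(const)
  expect_equal(wp$mean_power_w, 400)
  expect_equal(wp$max_power_w, 400)

  ramp <- wingate_trial(seq(0, 600, length.out = 301)[-1], fs_hz = 10)
  wpr <- wingate_powers(ramp, peak_window_s = 0.1)
  expect_equal(wpr$mean_power_w, 300, tolerance = 0.01)

  expect_error(wingate_powers(const, peak_window_s = 60), "longer than")

  set.seed(2)
  for (i in 1:10) {
    tr <- wingate_trial(stats::runif(300, 100, 700), fs_hz = 10)
    w <- wingate_powers(tr)
    expect_gte(w$max_power_w, w$mean_power_w)
  }
})

test_that("simulated wingate traces hit their configured mean and peak", {
  tr <- rebound:::simulate_wingate_trace(427, 515, fs_hz = 10,
                                         duration_s = 30)
  wp <- wingate_powers(tr, peak_window_s = 1)
  expect_equal(wp$mean_power_w, 427, tolerance = 1e-9)
  expect_equal(wp$max_power_w, 515, tolerance = 1e-9)
})
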