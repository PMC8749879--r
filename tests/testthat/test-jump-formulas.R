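# Ballistic formula layer: values frozen from independent symbolic
# evaluation, plus the algebraic identities the formulas must satisfy.

test_that("formulas reproduce independently computed reference values", {
  body <- body_params(72.4)
  # references computed symbolically (sympy) on m=72.4, g=9.81,
  # Tc=0.25 s, Tf=0.50 s
  expect_equal(flight_height(0.5), 0.3065625, tolerance = 1e-9)
  expect_equal(mean_power(body, 0.25, 0.5), 2969.77163815, tolerance = 1e-9)
  expect_equal(reactive_strength_index(0.3065625, 0.25), 1.22625,
               tolerance = 1e-9)
  expect_equal(leg_stiffness(body, 0.25, 0.5), 15487.5917864,
               tolerance = 1e-9)
  expect_equal(flight_time_from_height(0.2), 0.4038550218769218,
               tolerance = 1e-9)
})

test_that("zero and limit cases hold", {
  expect_equal(flight_height(0), 0)
  expect_equal(flight_time_from_height(0), 0)
  expect_equal(reactive_strength_index(0, 0.3), 0)
  # Tf = 0 collapses mean power to m g^2 Tc (1/pi - 1/4)
  body <- body_params(72.4)
  expect_equal(mean_power(body, 0.25, 0), 72.4 * 9.81^2 * 0.25 * (1 / pi - 0.25),
               tolerance = 1e-12)
})

test_that("height/flight-time round trip is exact", {
  tf <- seq(0.05, 0.9, by = 0.05)
  expect_equal(flight_time_from_height(flight_height(tf)), tf,
               tolerance = 1e-12)
  h <- seq(0, 0.6, by = 0.03)
  expect_equal(flight_height(flight_time_from_height(h)), h,
               tolerance = 1e-12)
})

test_that("mass enters power and stiffness linearly", {
  b1 <- body_params(60); b2 <- body_params(120)
  expect_equal(mean_power(b2, 0.3, 0.45), 2 * mean_power(b1, 0.3, 0.45))
  expect_equal(leg_stiffness(b2, 0.3, 0.45), 2 * leg_stiffness(b1, 0.3, 0.45))
  # RSI homogeneity in contact time
  expect_equal(reactive_strength_index(0.3, 0.5),
               reactive_strength_index(0.3, 0.25) / 2)
})

test_that("height grows with flight time; stiffness falls with contact share", {
  tf <- seq(0.2, 0.9, by = 0.01)
  expect_true(all(diff(flight_height(tf)) > 0))
  body <- body_params(72.4)
  # fixed cycle duration Tc + Tf, increasing Tc
  total <- 0.8
  tc <- seq(0.1, 0.5, by = 0.01)
  k <- vapply(tc, function(ci) leg_stiffness(body, ci, total - ci),
              numeric(1))
  expect_true(all(diff(k) < 0))
})

test_that("domain violations raise errors", {
  body <- body_params(72.4)
  expect_error(flight_height(-0.1), "non-negative")
  expect_error(flight_time_from_height(-1), "non-negative")
  expect_error(mean_power(body, 0, 0.5), "positive")
  expect_error(reactive_strength_index(0.3, 0), "positive")
  expect_error(leg_stiffness(body, 0, 0.5), "positive")
  expect_error(body_params(-3), "mass_kg")
  expect_error(body_params(72, g_ms2 = 0), "g_ms2")
})
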