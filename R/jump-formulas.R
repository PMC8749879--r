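## Ballistic jump parameters from contact and flight times.
##
## All four derived parameters are functions of the two durations an inertial
## sensor measures directly: the ground contact time Tc and the flight time Tf
## of each rebound jump. The flight-time method gives jump height from
## projectile kinematics; mean power and leg stiffness come from the
## spring-mass model of repeated hopping.

#' Body parameters for jump-metric computation
#'
#' @param mass_kg body mass in kg.
#' @param g_ms2 gravitational acceleration in m/s^2.
#' @return An object of class `body_params`.
#' @examples
#' body_params(72.4)
#' @export
body_params <- function(mass_kg, g_ms2 = GRAVITY_MS2) {
  check_scalar(mass_kg, "mass_kg", lower = 0, strict_lower = TRUE)
  check_scalar(g_ms2, "g_ms2", lower = 0, strict_lower = TRUE)
  structure(list(mass_kg = mass_kg, g_ms2 = g_ms2), class = "body_params")
}

#' Jump height from flight time
#'
#' Flight-time method: a body leaving the ground with vertical velocity `v`
#' is airborne for `Tf = 2 v / g`, so the apex height is
#' `h = g * Tf^2 / 8`.
#'
#' @param tf_s flight time in seconds (vectorized).
#' @param g_ms2 gravitational acceleration in m/s^2.
#' @return Maximum height in metres.
#' @examples
#' flight_height(0.5) # 0.3066 m
#' @seealso [flight_time_from_height()] for the inverse.
#' @export
flight_height <- function(tf_s, g_ms2 = GRAVITY_MS2) {
  if (any(!is.finite(tf_s)) || any(tf_s < 0))
    stop_domain("flight time must be finite and non-negative")
  check_scalar(g_ms2, "g_ms2", lower = 0, strict_lower = TRUE)
  g_ms2 * tf_s^2 / 8
}

#' Flight time that produces a given apex height
#'
#' Inverse of [flight_height()]: `Tf = sqrt(8 h / g)`.
#'
#' @param h_m apex height in metres (vectorized).
#' @param g_ms2 gravitational acceleration in m/s^2.
#' @return Flight duration in seconds.
#' @export
flight_time_from_height <- function(h_m, g_ms2 = GRAVITY_MS2) {
  if (any(!is.finite(h_m)) || any(h_m < 0))
    stop_domain("height must be finite and non-negative")
  check_scalar(g_ms2, "g_ms2", lower = 0, strict_lower = TRUE)
  sqrt(8 * h_m / g_ms2)
}

#' Mean exerted power over a rebound-jump cycle
#'
#' Flight-time estimate of the average mechanical power developed during the
#' contact phase of repeated rebound jumps:
#' \deqn{P = \frac{m g^2}{T_c}\left(\frac{T_f^2}{4} +
#'   \frac{T_c\,|T_c + T_f|}{\pi} - \frac{T_c^2}{4}\right)}
#' where `m` is body mass. The bracket has units of s^2, so `P` is in watts.
#'
#' @param body a [body_params()] object.
#' @param tc_s contact time in seconds (> 0, vectorized).
#' @param tf_s flight time in seconds (>= 0, vectorized).
#' @return Mean power in watts.
#' @examples
#' mean_power(body_params(72.4), tc_s = 0.25, tf_s = 0.50) # ~2970 W
#' @export
mean_power <- function(body, tc_s, tf_s) {
  stopifnot(inherits(body, "body_params"))
  if (any(!is.finite(tc_s)) || any(tc_s <= 0))
    stop_domain("contact time must be positive (division by Tc)")
  if (any(!is.finite(tf_s)) || any(tf_s < 0))
    stop_domain("flight time must be finite and non-negative")
  m <- body$mass_kg
  g <- body$g_ms2
  (m * g^2 / tc_s) * (tf_s^2 / 4 + tc_s * abs(tc_s + tf_s) / pi - tc_s^2 / 4)
}

#' Reactive strength index
#'
#' Jump height divided by ground contact time, `RSI = h_max / Tc`, a measure
#' of fast stretch-shortening-cycle capability (m/s).
#'
#' @param h_max_m jump height in metres (>= 0, vectorized).
#' @param tc_s contact time in seconds (> 0, vectorized).
#' @return RSI in m/s.
#' @export
reactive_strength_index <- function(h_max_m, tc_s) {
  if (any(!is.finite(h_max_m)) || any(h_max_m < 0))
    stop_domain("height must be finite and non-negative")
  if (any(!is.finite(tc_s)) || any(tc_s <= 0))
    stop_domain("contact time must be positive")
  h_max_m / tc_s
}

#' Spring-mass leg stiffness
#'
#' Average stiffness of the leg modeled as a linear spring during ground
#' contact of repeated hopping:
#' \deqn{K = \frac{m \pi (T_f + T_c)}{T_c^2\left(\frac{T_f + T_c}{\pi} -
#'   \frac{T_c}{4}\right)}}
#' The denominator is positive whenever `Tf > Tc * (pi/4 - 1)`, which holds
#' for every physiologically plausible rebound jump; it is checked anyway.
#'
#' @inheritParams mean_power
#' @return Stiffness in N/m.
#' @examples
#' leg_stiffness(body_params(72.4), tc_s = 0.25, tf_s = 0.50) # ~15488 N/m
#' @export
leg_stiffness <- function(body, tc_s, tf_s) {
  stopifnot(inherits(body, "body_params"))
  if (any(!is.finite(tc_s)) || any(tc_s <= 0))
    stop_domain("contact time must be positive")
  if (any(!is.finite(tf_s)) || any(tf_s < 0))
    stop_domain("flight time must be finite and non-negative")
  denom_core <- (tf_s + tc_s) / pi - tc_s / 4
  if (any(denom_core <= 0))
    stop_domain(paste0(
      "leg stiffness undefined: (Tf + Tc)/pi - Tc/4 <= 0 ",
      "(requires Tf > Tc * (pi/4 - 1) = %g s)"), max(tc_s) * (pi / 4 - 1))
  body$mass_kg * pi * (tf_s + tc_s) / (tc_s^2 * denom_core)
}
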