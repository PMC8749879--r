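## Session-level physiological and performance metrics.

#' Mean heart rate over a workout
#'
#' Arithmetic mean of the periodic heart-rate estimates across the whole
#' session. Missing samples (`NA`) are omitted, mirroring a device that drops
#' physiologically implausible estimates rather than interpolating them.
#'
#' @param series an [hr_series()].
#' @return Mean heart rate in bpm.
#' @export
mean_heart_rate <- function(series) {
  stopifnot(inherits(series, "hr_series"))
  ok <- !is.na(series$bpm)
  if (!any(ok))
    stop_domain("all heart-rate samples are missing")
  mean(series$bpm[ok])
}

#' Total covered distance from a GNSS track
#'
#' Sum of successive great-circle (haversine) segment lengths on a sphere of
#' radius 6,371,000 m. An optional speed gate drops segments implying an
#' implausible speed (GNSS spikes); it is off by default for clean tracks.
#'
#' @param track a [gnss_track()].
#' @param max_speed_ms segments faster than this (m/s) are dropped; `Inf`
#'   disables the gate. Sprinting athletes stay under ~12 m/s.
#' @return Total distance in metres.
#' @examples
#' trk <- gnss_track(time_s = c(0, 10), lat_deg = c(43.0, 43.0),
#'                   lon_deg = c(11.0, 11.001))
#' total_distance(trk)
#' @export
total_distance <- function(track, max_speed_ms = Inf) {
  stopifnot(inherits(track, "gnss_track"))
  n <- length(track$time_s)
  if (n < 2L)
    stop_domain("at least two track points are needed for a distance")
  p <- cbind(track$lon_deg, track$lat_deg)
  d <- geosphere::distHaversine(p[-n, , drop = FALSE], p[-1L, , drop = FALSE],
                                r = 6371000)
  if (is.finite(max_speed_ms)) {
    speed <- d / diff(track$time_s)
    d <- d[speed <= max_speed_ms]
  }
  sum(d)
}

#' Mean and peak power of a Wingate trial
#'
#' The mean is the time-average of the whole trace. The peak is the maximum
#' of a centred rolling mean of width `peak_window_s`: instantaneous maxima
#' are noise-dominated, so anaerobic peak power is conventionally reported
#' over a short window (1 s default).
#'
#' @param trial a [wingate_trial()].
#' @param peak_window_s width of the rolling-mean window in seconds; must be
#'   at least one sample period and no longer than the trial.
#' @return A named list with `mean_power_w` and `max_power_w`.
#' @export
wingate_powers <- function(trial, peak_window_s = 1) {
  stopifnot(inherits(trial, "wingate_trial"))
  check_scalar(peak_window_s, "peak_window_s", lower = 1 / trial$fs_hz)
  x <- trial$power_w
  k <- max(1L, round(peak_window_s * trial$fs_hz))
  if (k > length(x))
    stop_domain("peak window (%.1f s) longer than the trial (%.1f s)",
                peak_window_s, trial$duration_s)
  roll <- if (k == 1L) x else
    stats::filter(x, rep(1 / k, k), sides = 2)
  list(mean_power_w = mean(x), max_power_w = max(roll, na.rm = TRUE))
}
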