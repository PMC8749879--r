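## Sensor-trace containers shared by the simulator, the extractors and the
## CSV readers. All are light S3 records over numeric vectors; constructors
## validate the physical invariants once so downstream code can assume them.

#' Accelerometer trace
#'
#' A uniformly sampled vertical specific-force signal in units of g
#' (1 g = 9.81 m/s^2). An accelerometer at rest reads ~1 g; in free fall it
#' reads ~0 g — this contrast is what the jump event detector exploits.
#'
#' @param samples numeric vector of specific-force values in g.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param t0 timestamp of the first sample in seconds from session start.
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(samples, fs_hz, t0 = 0) {
  check_scalar(fs_hz, "fs_hz", lower = 0, strict_lower = TRUE)
  check_scalar(t0, "t0")
  if (length(samples) == 0L || !is.numeric(samples) || anyNA(samples))
    stop_domain("accelerometer trace must contain at least one finite sample")
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz, t0 = t0),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz, x$t0))
  invisible(x)
}

#' Heart-rate series
#'
#' Heart rate sampled at a fixed period (nominally every 5 s by the wrist
#' device). Missing estimates are encoded as `NA` and simply omitted from
#' averages — no interpolation is attempted.
#'
#' @param bpm numeric vector of heart-rate values in beats per minute;
#'   `NA` marks missing samples.
#' @param sample_period_s spacing between samples in seconds.
#' @return An object of class `hr_series`.
#' @export
hr_series <- function(bpm, sample_period_s = 5) {
  check_scalar(sample_period_s, "sample_period_s", lower = 0,
               strict_lower = TRUE)
  if (length(bpm) == 0L || !is.numeric(bpm))
    stop_domain("heart-rate series must contain at least one sample")
  ok <- !is.na(bpm)
  if (any(bpm[ok] <= 25 | bpm[ok] >= 250))
    stop_domain("heart-rate values must lie in (25, 250) bpm")
  structure(list(bpm = as.numeric(bpm), sample_period_s = sample_period_s),
            class = "hr_series")
}

#' GNSS position track
#'
#' @param time_s strictly increasing timestamps in seconds.
#' @param lat_deg latitudes in decimal degrees.
#' @param lon_deg longitudes in decimal degrees.
#' @return An object of class `gnss_track`.
#' @export
gnss_track <- function(time_s, lat_deg, lon_deg) {
  n <- length(time_s)
  if (n == 0L || length(lat_deg) != n || length(lon_deg) != n)
    stop_domain("GNSS track components must be non-empty and equal-length")
  if (anyNA(time_s) || any(diff(time_s) <= 0))
    stop_domain("GNSS timestamps must be strictly increasing")
  if (any(abs(lat_deg) > 90) || any(abs(lon_deg) > 180))
    stop_domain("GNSS coordinates out of range (|lat| <= 90, |lon| <= 180)")
  structure(list(time_s = as.numeric(time_s), lat_deg = as.numeric(lat_deg),
                 lon_deg = as.numeric(lon_deg)), class = "gnss_track")
}

#' Wingate power trace
#'
#' Instantaneous power output during a 30-s all-out cycling test.
#'
#' @param power_w non-negative instantaneous power samples in watts.
#' @param fs_hz sampling rate in Hz.
#' @param duration_nominal_s nominal test duration; the actual trace length
#'   must be within 10% of it.
#' @return An object of class `wingate_trial`.
#' @export
wingate_trial <- function(power_w, fs_hz, duration_nominal_s = 30) {
  check_scalar(fs_hz, "fs_hz", lower = 0, strict_lower = TRUE)
  if (length(power_w) == 0L || anyNA(power_w) || any(power_w < 0))
    stop_domain("power trace must be non-empty and non-negative")
  dur <- length(power_w) / fs_hz
  if (abs(dur - duration_nominal_s) > 0.1 * duration_nominal_s)
    stop_domain("trace duration %.1f s not within 10%% of nominal %.0f s",
                dur, duration_nominal_s)
  structure(list(power_w = as.numeric(power_w), fs_hz = fs_hz,
                 duration_s = dur), class = "wingate_trial")
}
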