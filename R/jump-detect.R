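## Contact/flight event detection in foot-mounted accelerometer traces.
##
## A foot-mounted accelerometer reads ~1 g standing, ~0 g in free fall and a
## large pulse during ground contact. Flight phases are therefore maximal runs
## of samples below a threshold well under 1 g; contacts are the intervals
## between consecutive flights. The first contact has no preceding flight and
## is anchored at the first sustained departure from quiet standing.

#' Default physiological validity bounds for repeated vertical jumps
#'
#' Contact times outside 0.10--1.00 s or flight times outside 0.20--0.90 s
#' are treated as detection artifacts and excluded from trial aggregates.
#' @return A list with elements `tc_s` and `tf_s`, each `c(min, max)`.
#' @export
jump_validity_bounds <- function() {
  list(tc_s = c(0.10, 1.00), tf_s = c(0.20, 0.90))
}

#' Detect jump events in an accelerometer trace
#'
#' Identifies flight phases as maximal runs of specific force below
#' `flight_threshold_g` lasting at least `min_flight_s`, merges flights
#' separated by implausibly short gaps (shorter than `min_contact_s`, i.e.
#' noise blips inside a flight), and pairs each flight with the preceding
#' contact interval. The first jump's contact start is found by scanning
#' backwards from the first takeoff to the last sample consistent with quiet
#' standing (deviation from 1 g below three times the noise level estimated
#' from the initial quiet segment).
#'
#' @param trace an [accel_trace()].
#' @param flight_threshold_g specific-force level (g) below which a sample is
#'   counted as free fall. 0.3 g splits the ~0 g flight level from the ~1 g
#'   standing level robustly under noise.
#' @param min_flight_s minimum duration of a flight phase in seconds.
#' @param min_contact_s minimum duration of a contact phase in seconds;
#'   flights separated by less are merged.
#' @return A data frame of class `jump_events` with one row per jump and
#'   columns `contact_start_s`, `takeoff_s`, `landing_s`, `tc_s`, `tf_s`.
#'   Zero rows when no flight is detected (not an error).
#' @examples
#' sim <- simulate_jump_trace(list(jump_spec(0.25, 0.5)), fs_hz = 100,
#'                            noise_sd_g = 0, seed = 1)
#' detect_jump_events(sim$trace)
#' @export
detect_jump_events <- function(trace, flight_threshold_g = 0.3,
                               min_flight_s = 0.08, min_contact_s = 0.05) {
  stopifnot(inherits(trace, "accel_trace"))
  check_scalar(flight_threshold_g, "flight_threshold_g", lower = 0,
               strict_lower = TRUE)
  check_scalar(min_flight_s, "min_flight_s", lower = 0, strict_lower = TRUE)
  check_scalar(min_contact_s, "min_contact_s", lower = 0, strict_lower = TRUE)

  x <- trace$samples
  fs <- trace$fs_hz
  n <- length(x)
  empty <- data.frame(contact_start_s = numeric(0), takeoff_s = numeric(0),
                      landing_s = numeric(0), tc_s = numeric(0),
                      tf_s = numeric(0))
  class(empty) <- c("jump_events", "data.frame")

  r <- rle(x < flight_threshold_g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fl <- which(r$values)
  if (length(fl) == 0L) return(empty)
  seg <- cbind(start = starts[fl], end = ends[fl])

  # merge flights separated by a gap too short to be a real contact
  min_gap <- min_contact_s * fs - 1e-9
  if (nrow(seg) > 1L) {
    keep <- list(seg[1L, ])
    for (i in seq_len(nrow(seg))[-1L]) {
      last <- keep[[length(keep)]]
      if (seg[i, "start"] - last["end"] - 1L < min_gap) {
        last["end"] <- seg[i, "end"]
        keep[[length(keep)]] <- last
      } else keep[[length(keep) + 1L]] <- seg[i, ]
    }
    seg <- do.call(rbind, keep)
  }

  # enforce minimum flight duration
  seg <- seg[(seg[, "end"] - seg[, "start"] + 1L) >= min_flight_s * fs - 1e-9,
             , drop = FALSE]
  # a flight starting at the very first sample has no preceding contact
  seg <- seg[seg[, "start"] > 1L, , drop = FALSE]
  if (nrow(seg) == 0L) return(empty)

  takeoff_idx <- seg[, "start"]
  landing_idx <- seg[, "end"] + 1L

  # first contact: end of the last sustained quiet-standing run before the
  # first takeoff. A single near-baseline sample inside the contact pulse
  # (e.g. the smooth return towards 1 g just before takeoff) must not count,
  # hence the >= 50 ms run requirement.
  quiet_n <- min(max(5L, round(0.25 * fs)), takeoff_idx[1L] - 1L)
  baseline <- stats::median(x[seq_len(quiet_n)])
  noise_sd <- stats::sd(x[seq_len(quiet_n)])
  if (!is.finite(noise_sd)) noise_sd <- 0
  thr_dev <- max(3 * noise_sd, 1e-4)
  min_quiet <- max(1L, round(0.05 * fs))
  pre_quiet <- abs(x[seq_len(takeoff_idx[1L] - 1L)] - baseline) <= thr_dev
  qr <- rle(pre_quiet)
  q_ends <- cumsum(qr$lengths)
  sustained <- qr$values & qr$lengths >= min_quiet
  onset_idx <- if (!any(sustained)) 1L else max(q_ends[sustained]) + 1L
  if (onset_idx >= takeoff_idx[1L]) onset_idx <- takeoff_idx[1L] - 1L

  contact_idx <- c(onset_idx, landing_idx[-length(landing_idx)])
  idx_t <- function(i) trace$t0 + (i - 1L) / fs
  ev <- data.frame(contact_start_s = idx_t(contact_idx),
                   takeoff_s = idx_t(takeoff_idx),
                   landing_s = idx_t(landing_idx))
  ev$tc_s <- ev$takeoff_s - ev$contact_start_s
  ev$tf_s <- ev$landing_s - ev$takeoff_s
  class(ev) <- c("jump_events", "data.frame")
  ev
}

#' Aggregate a repeated-jump trial into its six ballistic parameters
#'
#' Filters detected jump events to physiologically valid contact/flight
#' times, averages the valid durations, and computes jump height, mean power,
#' reactive strength index and leg stiffness from the aggregate `(Tc, Tf)`
#' pair. Computing the derived parameters from the aggregated durations (not
#' averaging per-jump parameters) keeps the internal consistency
#' `h_max = g * Tf^2 / 8` exactly true for the reported aggregate.
#'
#' @param events a `jump_events` data frame from [detect_jump_events()], or
#'   any data frame with `tc_s` and `tf_s` columns.
#' @param body a [body_params()] object.
#' @param validity validity bounds as produced by [jump_validity_bounds()].
#' @return An object of class `bosco_result`: a list with `h_max_m`,
#'   `mean_power_w`, `rsi_ms`, `stiffness_nm`, `tc_s`, `tf_s`, `n_jumps`.
#' @export
bosco_summary <- function(events, body, validity = jump_validity_bounds()) {
  stopifnot(is.data.frame(events), inherits(body, "body_params"))
  if (nrow(events) == 0L)
    stop_domain("no jump events to aggregate")
  tc_ok <- events$tc_s >= validity$tc_s[1] & events$tc_s <= validity$tc_s[2]
  tf_ok <- events$tf_s >= validity$tf_s[1] & events$tf_s <= validity$tf_s[2]
  valid <- tc_ok & tf_ok
  if (!any(valid)) {
    culprit <- if (!any(tc_ok)) "contact-time" else "flight-time"
    stop_domain("all %d events removed by the %s validity filter [%g, %g] s",
                nrow(events), culprit,
                if (!any(tc_ok)) validity$tc_s[1] else validity$tf_s[1],
                if (!any(tc_ok)) validity$tc_s[2] else validity$tf_s[2])
  }
  tc <- mean(events$tc_s[valid])
  tf <- mean(events$tf_s[valid])
  h <- flight_height(tf, body$g_ms2)
  res <- list(h_max_m = h,
              mean_power_w = mean_power(body, tc, tf),
              rsi_ms = reactive_strength_index(h, tc),
              stiffness_nm = leg_stiffness(body, tc, tf),
              tc_s = tc, tf_s = tf, n_jumps = sum(valid))
  class(res) <- "bosco_result"
  res
}

#' @export
print.bosco_result <- function(x, ...) {
  cat(sprintf(paste0("<bosco_result> %d jumps: h_max %.3f m, power %.0f W, ",
                     "RSI %.2f m/s, stiffness %.0f N/m (Tc %.3f s, Tf %.3f s)\n"),
              x$n_jumps, x$h_max_m, x$mean_power_w, x$rsi_ms, x$stiffness_nm,
              x$tc_s, x$tf_s))
  invisible(x)
}
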