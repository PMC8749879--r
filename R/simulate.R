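## Synthetic-cohort generator.
##
## Produces physically grounded synthetic inputs with exact ground truth:
## repeated-jump accelerometry (1 g standing, 0 g free fall, raised-cosine
## contact pulse), 5-s heart-rate series, shuttle-run GNSS tracks of fixed
## prescribed geometry, Wingate power traces, and a full multi-week cohort
## with a configurable downfall/recovery trajectory and two training
## subgroups. Every stochastic element is seeded; identical (config, seed)
## pairs yield bit-identical datasets.

#' Specification of one rebound jump
#'
#' @param tc_s ground contact duration in seconds (> 0).
#' @param tf_s flight duration in seconds (> 0).
#' @param peak_contact_gain peak specific force during contact, as a multiple
#'   of g (> 1). Repeated vertical jumps typically peak at 2--4 g at the foot.
#' @return An object of class `jump_spec`.
#' @export
jump_spec <- function(tc_s, tf_s, peak_contact_gain = 2.5) {
  check_scalar(tc_s, "tc_s", lower = 0, strict_lower = TRUE)
  check_scalar(tf_s, "tf_s", lower = 0, strict_lower = TRUE)
  check_scalar(peak_contact_gain, "peak_contact_gain", lower = 1,
               strict_lower = TRUE)
  structure(list(tc_s = tc_s, tf_s = tf_s,
                 peak_contact_gain = peak_contact_gain), class = "jump_spec")
}

#' Simulate a foot-mounted accelerometer trace of repeated jumps
#'
#' Builds a specific-force signal that reads 1 g during quiet standing, 0 g
#' during each flight (ideal free fall) and a smooth half-sine pulse rising
#' to `peak_contact_gain` during each contact. Phase boundaries are placed on
#' the sample grid by cumulative rounding, so each realized phase duration is
#' within one sample period of its specification; the realized boundaries are
#' returned as exact sample indices. A final landing pulse and a quiet tail
#' close the trace. Gaussian sensor noise of the stated standard deviation is
#' added on top.
#'
#' @param jumps non-empty list of [jump_spec()] objects.
#' @param fs_hz sampling rate, at least 50 Hz so the shortest realistic
#'   flight spans several samples.
#' @param noise_sd_g additive Gaussian noise standard deviation in g.
#' @param lead_s quiet-standing padding before the first contact, seconds.
#' @param tail_s quiet padding after the final landing, seconds.
#' @param seed integer seed for the noise draw.
#' @return A list with `trace` (an [accel_trace()]) and `events`, a data
#'   frame of ground-truth boundaries per jump: sample indices
#'   `contact_start_idx`, `takeoff_idx`, `landing_idx` (1-based), realized
#'   durations `tc_s`, `tf_s`, and the requested `tc_spec_s`, `tf_spec_s`.
#' @export
simulate_jump_trace <- function(jumps, fs_hz, noise_sd_g = 0.02, lead_s = 2,
                                tail_s = 1, seed = 1L) {
  if (length(jumps) == 0L)
    stop_domain("empty jump specification")
  if (inherits(jumps, "jump_spec")) jumps <- list(jumps)
  stopifnot(all(vapply(jumps, inherits, logical(1), "jump_spec")))
  check_scalar(fs_hz, "fs_hz", lower = 50)
  check_scalar(noise_sd_g, "noise_sd_g", lower = 0)
  check_scalar(lead_s, "lead_s", lower = 0)
  short <- vapply(jumps, function(j) j$tf_s * fs_hz < 3, logical(1))
  if (any(short))
    stop_domain("flight time of jump %d spans fewer than 3 samples at %g Hz",
                which(short)[1], fs_hz)

  # segment table: (duration, kind, gain); kinds: quiet, contact, flight
  segs <- list(list(d = lead_s, kind = "quiet", gain = NA))
  for (j in jumps) {
    segs <- c(segs, list(list(d = j$tc_s, kind = "contact",
                              gain = j$peak_contact_gain),
                         list(d = j$tf_s, kind = "flight", gain = NA)))
  }
  last <- jumps[[length(jumps)]]
  segs <- c(segs, list(list(d = last$tc_s, kind = "contact",
                            gain = last$peak_contact_gain),
                       list(d = tail_s, kind = "quiet", gain = NA)))

  durs <- vapply(segs, `[[`, numeric(1), "d")
  bounds <- round(cumsum(c(0, durs)) * fs_hz)  # sample-count boundaries
  n_total <- bounds[length(bounds)]
  x <- numeric(n_total)
  for (i in seq_along(segs)) {
    a <- bounds[i] + 1L
    b <- bounds[i + 1L]
    len <- b - a + 1L
    if (len <= 0L) next
    x[a:b] <- switch(segs[[i]]$kind,
      quiet = 1,
      flight = 0,
      contact = 1 + (segs[[i]]$gain - 1) *
        sin(pi * (seq_len(len) - 0.5) / len))
  }
  if (noise_sd_g > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    x <- x + stats::rnorm(n_total, 0, noise_sd_g)
  }

  n_j <- length(jumps)
  seg_i <- 2 * seq_len(n_j)          # index of each jump's contact segment
  contact_start_idx <- bounds[seg_i] + 1L
  takeoff_idx <- bounds[seg_i + 1L] + 1L
  landing_idx <- bounds[seg_i + 2L] + 1L
  events <- data.frame(
    contact_start_idx = contact_start_idx,
    takeoff_idx = takeoff_idx,
    landing_idx = landing_idx,
    tc_s = (takeoff_idx - contact_start_idx) / fs_hz,
    tf_s = (landing_idx - takeoff_idx) / fs_hz,
    tc_spec_s = vapply(jumps, `[[`, numeric(1), "tc_s"),
    tf_spec_s = vapply(jumps, `[[`, numeric(1), "tf_s"))
  list(trace = accel_trace(x, fs_hz), events = events)
}

#' Cohort / study-design configuration
#'
#' Defaults mirror the monitored study design this package targets: 8
#' athletes, 4 weeks with session counts (2, 2, 1, 1), performance nadir in
#' week 2, and two lockdown-training subgroups ("<45min" vs ">=45min" of
#' daily self-administered training) with the shorter-training group showing
#' higher heart rates and deeper fatigue effects.
#'
#' Fatigue effects are multiplicative post/pre ratios in (0, 1]; the Wingate
#' trajectory keeps a residual deficit at week 4 while the ballistic (Bosco)
#' trajectory recovers essentially fully, so pre/post differences lose
#' significance there.
#'
#' @param n_athletes number of athletes.
#' @param n_weeks number of study weeks.
#' @param sessions_per_week integer vector of per-week session counts.
#' @param nadir_week week of worst performance (deepest fatigue effect).
#' @param hr_weekly_bpm target mean heart rate per week, bpm.
#' @param wingate_effect_by_week post/pre multiplicative fatigue effect on
#'   Wingate powers, per week; minimum must sit at `nadir_week` and values
#'   must increase strictly afterwards.
#' @param bosco_effect_by_week same for the Bosco flight time (contact time
#'   scales inversely: fatigue lengthens contacts and shortens flights).
#' @param recovery_slope weekly improvement of the fatigue effect after the
#'   nadir used when effect vectors are generated rather than supplied; kept
#'   for reference when explicit vectors are given.
#' @param baseline_by_param named list of pre-effort baselines:
#'   `wingate_mean_power_w`, `wingate_max_power_w`, `bosco_tc_s`,
#'   `bosco_tf_s`.
#' @param subgroup_offsets named list with `hr_bpm` (additive bpm offset per
#'   group) and `fatigue_depth` (multiplier on the weekly fatigue *deficit*
#'   `1 - effect` per group; > 1 deepens fatigue where fatigue exists and
#'   leaves recovered weeks untouched, so subgroup contrasts fade as the
#'   cohort recovers).
#' @param noise_cv coefficient of variation of session-to-session
#'   measurement noise on scalar performance values (0 disables all
#'   stochastic variation of scalars).
#' @param between_cv named list of between-athlete CVs: `power`, `duration`;
#'   plus `hr_bpm_sd`, an additive between-athlete HR spread in bpm.
#' @param session_duration_min workout duration in minutes (HR series
#'   length = duration * 60 / 5 samples).
#' @param phase_min durations in minutes of the five shuttle phases;
#'   the protocol prescribes 5 min for the first and last.
#' @param rest_min rest between phases, minutes.
#' @param shuttle_m shuttle leg length, metres.
#' @param shuttle_legs legs per work bout for the five phases (two-way
#'   shuttles in phases 1 and 5, three-way in the middle phases).
#' @param gnss_jitter_m per-point Gaussian position jitter of simulated GNSS
#'   tracks, metres; 0 gives exactly reproducible path lengths.
#' @param bosco_duration_s,bosco_fs_hz repeated-jump trial duration and
#'   accelerometer rate.
#' @param accel_noise_sd_g accelerometer noise sd, g.
#' @param wingate_fs_hz,wingate_duration_s Wingate trace rate and duration.
#' @param seed default seed used by [simulate_cohort()].
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_athletes = 8L,
                          n_weeks = 4L,
                          sessions_per_week = c(2L, 2L, 1L, 1L),
                          nadir_week = 2L,
                          hr_weekly_bpm = c(157, 158, 146, 141),
                          wingate_effect_by_week = c(0.90, 0.80, 0.92, 0.94),
                          bosco_effect_by_week = c(0.93, 0.87, 0.95, 0.995),
                          recovery_slope = 0.06,
                          baseline_by_param = list(
                            wingate_mean_power_w = 427,
                            wingate_max_power_w = 515,
                            bosco_tc_s = 0.30,
                            bosco_tf_s = 0.50),
                          subgroup_offsets = list(
                            hr_bpm = c("<45min" = 6, ">=45min" = 0),
                            fatigue_depth = c("<45min" = 1.4, ">=45min" = 1)),
                          noise_cv = 0.04,
                          between_cv = list(power = 0.15, duration = 0.06,
                                            hr_bpm_sd = 4),
                          session_duration_min = 45,
                          phase_min = c(5, 5, 5, 5, 5),
                          rest_min = 2,
                          shuttle_m = 25,
                          shuttle_legs = c(2L, 3L, 3L, 3L, 2L),
                          gnss_jitter_m = 0.5,
                          bosco_duration_s = 30,
                          bosco_fs_hz = 100,
                          accel_noise_sd_g = 0.02,
                          wingate_fs_hz = 10,
                          wingate_duration_s = 30,
                          seed = 1L) {
  cfg <- list(n_athletes = as.integer(n_athletes),
              n_weeks = as.integer(n_weeks),
              sessions_per_week = as.integer(sessions_per_week),
              nadir_week = as.integer(nadir_week),
              hr_weekly_bpm = hr_weekly_bpm,
              wingate_effect_by_week = wingate_effect_by_week,
              bosco_effect_by_week = bosco_effect_by_week,
              recovery_slope = recovery_slope,
              baseline_by_param = baseline_by_param,
              subgroup_offsets = subgroup_offsets,
              noise_cv = noise_cv,
              between_cv = between_cv,
              session_duration_min = session_duration_min,
              phase_min = phase_min, rest_min = rest_min,
              shuttle_m = shuttle_m, shuttle_legs = as.integer(shuttle_legs),
              gnss_jitter_m = gnss_jitter_m,
              bosco_duration_s = bosco_duration_s,
              bosco_fs_hz = bosco_fs_hz,
              accel_noise_sd_g = accel_noise_sd_g,
              wingate_fs_hz = wingate_fs_hz,
              wingate_duration_s = wingate_duration_s,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_athletes < 2L) stop_domain("need at least 2 athletes")
  if (length(cfg$sessions_per_week) != cfg$n_weeks)
    stop_domain("sessions_per_week must have one entry per week")
  if (any(cfg$sessions_per_week < 1L))
    stop_domain("every week needs at least one session")
  if (cfg$nadir_week < 1L || cfg$nadir_week > cfg$n_weeks)
    stop_domain("nadir_week must lie in 1..n_weeks")
  for (nm in c("hr_weekly_bpm", "wingate_effect_by_week",
               "bosco_effect_by_week"))
    if (length(cfg[[nm]]) != cfg$n_weeks)
      stop_domain("`%s` must have one entry per week", nm)
  for (nm in c("wingate_effect_by_week", "bosco_effect_by_week")) {
    eff <- cfg[[nm]]
    if (any(eff <= 0 | eff > 1))
      stop_domain("fatigue effects in `%s` must lie in (0, 1]", nm)
    if (diff(range(eff)) > 0) {          # constant = null (no-week-effect) cfg
      if (which.min(eff) != cfg$nadir_week)
        stop_domain("`%s` minimum must sit at nadir_week = %d", nm,
                    cfg$nadir_week)
      after <- eff[cfg$nadir_week:cfg$n_weeks]
      if (length(after) > 1L && any(diff(after) <= 0))
        stop_domain("`%s` must increase strictly after the nadir week", nm)
    }
  }
  if (cfg$noise_cv < 0) stop_domain("noise_cv must be >= 0")
  if (length(cfg$phase_min) != length(cfg$shuttle_legs))
    stop_domain("phase_min and shuttle_legs must align")
  invisible(cfg)
}

#' Prescribed total distance of the shuttle-run fatigue protocol
#'
#' Each phase consists of 20-s cycles (10 s of work, 10 s of rest); a work
#' bout covers `legs * shuttle_m` metres. The prescribed distance is fixed by
#' the protocol geometry and therefore identical for every session.
#'
#' @param cfg a [cohort_config()].
#' @return Total prescribed path length in metres.
#' @export
prescribed_distance <- function(cfg = cohort_config()) {
  cycles <- floor(cfg$phase_min * 60 / 20)
  sum(cycles * cfg$shuttle_legs * cfg$shuttle_m)
}

## deterministic sub-seed derivation (kept under 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483647)
}

simulate_hr_trace <- function(mean_bpm, duration_s, noise_sd_bpm) {
  n <- round(duration_s / 5)
  t <- seq_len(n) * 5
  # warm-up rise then plateau with slow drift; centred so the series mean is
  # exactly the requested value when noise is zero
  shape <- -18 * exp(-t / 240) + 4 * sin(2 * pi * t / duration_s)
  bpm <- mean_bpm + (shape - mean(shape))
  if (noise_sd_bpm > 0) bpm <- bpm + stats::rnorm(n, 0, noise_sd_bpm)
  hr_series(pmin(pmax(bpm, 30), 240), sample_period_s = 5)
}

simulate_gnss_trace <- function(cfg, origin = c(lat = 43.747, lon = 11.335)) {
  leg_m <- cfg$shuttle_m
  t <- 0
  xs <- 0; ts <- 0
  pos <- 0; dir <- 1
  for (ph in seq_along(cfg$phase_min)) {
    cycles <- floor(cfg$phase_min[ph] * 60 / 20)
    legs <- cfg$shuttle_legs[ph]
    for (cy in seq_len(cycles)) {
      leg_t <- 10 / legs
      for (lg in seq_len(legs)) {
        pos <- pos + dir * leg_m
        dir <- -dir
        t <- t + leg_t
        ts <- c(ts, t); xs <- c(xs, pos)
      }
      t <- t + 10                       # within-cycle rest
      ts <- c(ts, t); xs <- c(xs, pos)
    }
    if (ph < length(cfg$phase_min)) {
      t <- t + cfg$rest_min * 60        # between-phase rest
      ts <- c(ts, t); xs <- c(xs, pos)
    }
  }
  ys <- numeric(length(xs))
  if (cfg$gnss_jitter_m > 0) {
    xs <- xs + stats::rnorm(length(xs), 0, cfg$gnss_jitter_m)
    ys <- ys + stats::rnorm(length(ys), 0, cfg$gnss_jitter_m)
  }
  r_earth <- 6371000
  lat <- origin[["lat"]] + (ys / r_earth) * 180 / pi
  lon <- origin[["lon"]] +
    (xs / (r_earth * cos(origin[["lat"]] * pi / 180))) * 180 / pi
  gnss_track(ts, lat, lon)
}

simulate_wingate_trace <- function(mean_w, max_w, fs_hz, duration_s,
                                   peak_window_s = 1) {
  n <- round(duration_s * fs_hz)
  t <- (seq_len(n) - 0.5) / fs_hz
  # all-out profile: fast rise, exponential decay, pedal-stroke ripple
  shape <- ifelse(t < 2, t / 2, exp(-(t - 2) / 20)) +
    0.02 * sin(2 * pi * 1.5 * t)
  m_s <- mean(shape)
  k <- max(1L, round(peak_window_s * fs_hz))
  roll <- stats::filter(shape, rep(1 / k, k), sides = 2)
  peak_s <- max(roll, na.rm = TRUE)
  if (max_w < mean_w) stop_domain("max power below mean power")
  beta <- (max_w - mean_w) / (peak_s - m_s)
  alpha <- mean_w - beta * m_s
  wingate_trial(pmax(alpha + beta * shape, 0), fs_hz = fs_hz,
                duration_nominal_s = duration_s)
}

mult_noise <- function(n, cv) {
  if (cv <= 0) rep(1, n) else 1 + stats::rnorm(n, 0, cv)
}

#' Simulate one athlete training session
#'
#' Draws the session's scalar parameters (mean heart rate, covered distance,
#' pre/post Wingate powers and pre/post Bosco outcomes) around the athlete's
#' baselines and the configured weekly levels, with multiplicative Gaussian
#' measurement noise of CV `cfg$noise_cv`; post-effort values equal
#' pre-effort values times the week's fatigue effect (times noise). With
#' `include_traces = TRUE` the corresponding raw traces are also generated.
#'
#' @param athlete one row of the athlete table produced by
#'   [simulate_cohort()] (a list/data.frame row with `athlete_id`, `mass_kg`,
#'   `training_group` and baseline columns).
#' @param week 1-based week index.
#' @param cfg a [cohort_config()].
#' @param seed integer seed.
#' @param include_traces generate raw HR/GNSS/Wingate/accelerometer traces?
#' @return A list of class `session_record` with fields `athlete_id`, `week`,
#'   `scalars` (named list), `truth` (the noiseless values) and optionally
#'   `traces`.
#' @export
simulate_session <- function(athlete, week, cfg = cohort_config(),
                             seed = 1L, include_traces = FALSE) {
  if (week < 1L || week > cfg$n_weeks)
    stop_domain("week %d outside configured range 1..%d", week, cfg$n_weeks)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  grp <- athlete$training_group
  hr_off <- cfg$subgroup_offsets$hr_bpm[[grp]] +
    (athlete$hr_offset_bpm %||% 0)
  depth <- cfg$subgroup_offsets$fatigue_depth[[grp]]
  eff_w <- max(1e-6, 1 - (1 - cfg$wingate_effect_by_week[week]) * depth)
  eff_b <- max(1e-6, 1 - (1 - cfg$bosco_effect_by_week[week]) * depth)
  cv <- cfg$noise_cv

  truth <- list(
    hr_mean = cfg$hr_weekly_bpm[week] + hr_off,
    distance_m = prescribed_distance(cfg),
    wingate_mean_pre = athlete$wingate_mean_base %||%
      cfg$baseline_by_param$wingate_mean_power_w,
    wingate_max_pre = athlete$wingate_max_base %||%
      cfg$baseline_by_param$wingate_max_power_w,
    bosco_tc_pre = athlete$bosco_tc_base %||% cfg$baseline_by_param$bosco_tc_s,
    bosco_tf_pre = athlete$bosco_tf_base %||% cfg$baseline_by_param$bosco_tf_s,
    wingate_effect = eff_w, bosco_effect = eff_b)

  sc <- list()
  sc$hr_mean <- truth$hr_mean * mult_noise(1, 0.25 * cv)
  sc$distance_m <- truth$distance_m * mult_noise(1, 0.5 * cv)
  sc$wingate_mean_power_pre <- truth$wingate_mean_pre * mult_noise(1, cv)
  sc$wingate_max_power_pre <- max(truth$wingate_max_pre * mult_noise(1, cv),
                                  sc$wingate_mean_power_pre)
  sc$wingate_mean_power_post <- sc$wingate_mean_power_pre * eff_w *
    mult_noise(1, cv)
  sc$wingate_max_power_post <- max(sc$wingate_max_power_pre * eff_w *
                                     mult_noise(1, cv),
                                   sc$wingate_mean_power_post)
  tc_pre <- truth$bosco_tc_pre * mult_noise(1, cv)
  tf_pre <- truth$bosco_tf_pre * mult_noise(1, cv)
  tc_post <- tc_pre / eff_b * mult_noise(1, cv)
  tf_post <- tf_pre * eff_b * mult_noise(1, cv)
  body <- body_params(athlete$mass_kg)
  for (phase in c("pre", "post")) {
    tc <- if (phase == "pre") tc_pre else tc_post
    tf <- if (phase == "pre") tf_pre else tf_post
    h <- flight_height(tf)
    sc[[paste0("bosco_tc_", phase)]] <- tc
    sc[[paste0("bosco_tf_", phase)]] <- tf
    sc[[paste0("bosco_h_max_", phase)]] <- h
    sc[[paste0("bosco_mean_power_", phase)]] <- mean_power(body, tc, tf)
    sc[[paste0("bosco_rsi_", phase)]] <- reactive_strength_index(h, tc)
    sc[[paste0("bosco_stiffness_", phase)]] <- leg_stiffness(body, tc, tf)
  }

  traces <- NULL
  if (include_traces) {
    dur_s <- cfg$session_duration_min * 60
    traces <- list(
      hr = simulate_hr_trace(sc$hr_mean, dur_s, noise_sd_bpm = 60 * 0.25 * cv),
      gnss = simulate_gnss_trace(cfg),
      wingate_pre = simulate_wingate_trace(
        sc$wingate_mean_power_pre, sc$wingate_max_power_pre,
        cfg$wingate_fs_hz, cfg$wingate_duration_s),
      bosco_pre = simulate_bosco_trial(tc_pre, tf_pre, cfg,
                                       seed = derive_seed(seed, 11)),
      bosco_post = simulate_bosco_trial(tc_post, tf_post, cfg,
                                        seed = derive_seed(seed, 13)))
    pre_tr <- traces$wingate_pre
    ratio <- sc$wingate_mean_power_post / sc$wingate_mean_power_pre
    traces$wingate_post <- wingate_trial(pre_tr$power_w * ratio,
                                         fs_hz = pre_tr$fs_hz,
                                         duration_nominal_s =
                                           cfg$wingate_duration_s)
  }

  structure(list(athlete_id = athlete$athlete_id, week = as.integer(week),
                 scalars = sc, truth = truth, traces = traces, seed = seed),
            class = "session_record")
}

## repeated-jump trial trace around session-level (tc, tf), with mild
## jump-to-jump variability
simulate_bosco_trial <- function(tc_s, tf_s, cfg, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cycle <- tc_s + tf_s
  n_jumps <- max(1L, floor((cfg$bosco_duration_s - 2) / cycle))
  jit <- 0.5 * cfg$noise_cv
  jumps <- lapply(seq_len(n_jumps), function(i)
    jump_spec(tc_s * mult_noise(1, jit), tf_s * mult_noise(1, jit)))
  simulate_jump_trace(jumps, fs_hz = cfg$bosco_fs_hz,
                      noise_sd_g = cfg$accel_noise_sd_g, lead_s = 2,
                      seed = derive_seed(seed, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete multi-week study
#'
#' Generates the athlete roster (anthropometrics drawn around the cohort
#' means, two equal training subgroups, per-athlete performance baselines),
#' then simulates every session of every week. Scalar parameters are always
#' produced; raw traces are optional. The returned dataset retains full
#' ground truth.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer seed; defaults to `cfg$seed`.
#' @param include_traces also generate raw traces for every session (slower).
#' @return An object of class `study_dataset`: list with `athletes` (data
#'   frame), `sessions` (list of `session_record`), `parameters` (tidy data
#'   frame: `athlete_id`, `week`, `session_id`, `parameter`, `phase`,
#'   `value`), `config`, `seed`, `ground_truth`.
#' @examples
#' ds <- simulate_cohort(cohort_config(noise_cv = 0), seed = 7)
#' nrow(ds$athletes)      # 8
#' length(ds$sessions)    # 48
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = cfg$seed,
                            include_traces = FALSE) {
  validate_cohort_config(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n <- cfg$n_athletes
  groups <- rep(names(cfg$subgroup_offsets$hr_bpm), length.out = n)
  b <- cfg$baseline_by_param
  bc <- cfg$between_cv
  athletes <- data.frame(
    athlete_id = sprintf("A%02d", seq_len(n)),
    mass_kg = pmax(stats::rnorm(n, 72.4, 8.3), 50),
    height_cm = stats::rnorm(n, 180.8, 6.3),
    age_y = pmax(round(stats::rnorm(n, 24.0, 3.3)), 16),
    training_group = groups,
    hr_offset_bpm = stats::rnorm(n, 0, bc$hr_bpm_sd),
    wingate_mean_base = b$wingate_mean_power_w * mult_noise(n, bc$power),
    wingate_max_base = NA_real_,
    bosco_tc_base = b$bosco_tc_s * mult_noise(n, bc$duration),
    bosco_tf_base = b$bosco_tf_s * mult_noise(n, bc$duration),
    stringsAsFactors = FALSE)
  # peak power scales with the athlete's mean-power baseline
  athletes$wingate_max_base <- athletes$wingate_mean_base *
    (b$wingate_max_power_w / b$wingate_mean_power_w) *
    mult_noise(n, 0.3 * bc$power)
  if (cfg$noise_cv == 0) {
    # noiseless construction: no between-athlete spread either, so weekly
    # aggregates equal configured truth exactly
    athletes$hr_offset_bpm <- 0
    athletes$wingate_mean_base <- b$wingate_mean_power_w
    athletes$wingate_max_base <- b$wingate_max_power_w
    athletes$bosco_tc_base <- b$bosco_tc_s
    athletes$bosco_tf_base <- b$bosco_tf_s
  }

  sessions <- list()
  k <- 0L
  start <- as.Date("2020-05-25")
  for (w in seq_len(cfg$n_weeks)) {
    for (s in seq_len(cfg$sessions_per_week[w])) {
      for (i in seq_len(n)) {
        k <- k + 1L
        rec <- simulate_session(as.list(athletes[i, ]), w, cfg,
                                seed = derive_seed(seed, k),
                                include_traces = include_traces)
        rec$session_id <- sprintf("W%dS%d", w, s)
        rec$date <- as.character(start + (w - 1L) * 7L + s)
        sessions[[k]] <- rec
      }
    }
  }

  parameters <- do.call(rbind, lapply(sessions, session_parameter_rows))
  structure(list(athletes = athletes, sessions = sessions,
                 parameters = parameters, config = cfg, seed = seed,
                 ground_truth = list(
                   prescribed_distance_m = prescribed_distance(cfg),
                   wingate_effect_by_week = cfg$wingate_effect_by_week,
                   bosco_effect_by_week = cfg$bosco_effect_by_week,
                   hr_weekly_bpm = cfg$hr_weekly_bpm)),
            class = "study_dataset")
}

## tidy long rows for one session's scalar parameters
session_parameter_rows <- function(rec) {
  sc <- rec$scalars
  single <- data.frame(parameter = c("hr_mean", "distance"),
                       phase = "session",
                       value = c(sc$hr_mean, sc$distance_m),
                       stringsAsFactors = FALSE)
  pp_params <- c("wingate_mean_power", "wingate_max_power", "bosco_h_max",
                 "bosco_mean_power", "bosco_rsi", "bosco_stiffness",
                 "bosco_tc", "bosco_tf")
  pp <- do.call(rbind, lapply(pp_params, function(p)
    data.frame(parameter = p, phase = c("pre", "post"),
               value = c(sc[[paste0(p, "_pre")]], sc[[paste0(p, "_post")]]),
               stringsAsFactors = FALSE)))
  out <- rbind(single, pp)
  out$athlete_id <- rec$athlete_id
  out$week <- rec$week
  out$session_id <- rec$session_id
  out[, c("athlete_id", "week", "session_id", "parameter", "phase", "value")]
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(paste0("<study_dataset> %d athletes, %d sessions over %d ",
                     "weeks (seed %d)%s\n"),
              nrow(x$athletes), length(x$sessions), x$config$n_weeks,
              x$seed,
              if (!is.null(x$sessions[[1]]$traces)) ", with traces" else ""))
  invisible(x)
}
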