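## CSV readers/writers for sensor traces and study directories.
##
## Every trace file starts with one comment line declaring the trace kind and
## units, so a heart-rate file can never be silently read as an
## accelerometer trace and g / (m/s^2) confusion is caught at load time.
## Timestamps are seconds from session start; session dates live in the
## manifest.

trace_kinds <- function() {
  list(
    accel = list(cols = c("time_s", "accel_g"),
                 units = "time_s=s, accel_g=g (1 g = 9.81 m/s^2)"),
    hr    = list(cols = c("time_s", "bpm"),
                 units = "time_s=s, bpm=beats/min"),
    gnss  = list(cols = c("time_s", "lat_deg", "lon_deg"),
                 units = "time_s=s, lat_deg=deg, lon_deg=deg"),
    power = list(cols = c("time_s", "power_w"),
                 units = "time_s=s, power_w=W"))
}

trace_header <- function(kind) {
  sprintf("# rebound trace: %s; units: %s", kind, trace_kinds()[[kind]]$units)
}

#' Write a sensor trace to CSV
#'
#' @param x an [accel_trace()], [hr_series()], [gnss_track()] or
#'   [wingate_trial()] matching `kind`.
#' @param path output file path.
#' @param kind one of `"accel"`, `"hr"`, `"gnss"`, `"power"`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path, kind = c("accel", "hr", "gnss",
                                              "power")) {
  kind <- match.arg(kind)
  df <- switch(kind,
    accel = {
      stopifnot(inherits(x, "accel_trace"))
      data.frame(time_s = x$t0 + (seq_along(x$samples) - 1) / x$fs_hz,
                 accel_g = x$samples)
    },
    hr = {
      stopifnot(inherits(x, "hr_series"))
      data.frame(time_s = (seq_along(x$bpm) - 1) * x$sample_period_s,
                 bpm = x$bpm)
    },
    gnss = {
      stopifnot(inherits(x, "gnss_track"))
      data.frame(time_s = x$time_s, lat_deg = x$lat_deg,
                 lon_deg = x$lon_deg)
    },
    power = {
      stopifnot(inherits(x, "wingate_trial"))
      data.frame(time_s = (seq_along(x$power_w) - 1) / x$fs_hz,
                 power_w = x$power_w)
    })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(trace_header(kind), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a sensor trace from CSV
#'
#' Validates the kind/units header line, the column contract, row
#' well-formedness (malformed rows are reported with their line number) and
#' timestamp monotonicity, then returns the matching typed series.
#'
#' @param path CSV file written by [write_trace_csv()] (or following the
#'   same contract).
#' @param kind one of `"accel"`, `"hr"`, `"gnss"`, `"power"`.
#' @return An [accel_trace()], [hr_series()], [gnss_track()] or
#'   [wingate_trial()].
#' @export
read_trace_csv <- function(path, kind = c("accel", "hr", "gnss", "power")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  first <- readLines(path, n = 1L)
  expect <- sprintf("# rebound trace: %s;", kind)
  if (length(first) == 0L || !startsWith(first, expect))
    stop_domain("%s: missing or mismatched units header (expected %s kind)",
                path, kind)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = "numeric")
  spec <- trace_kinds()[[kind]]
  if (!identical(names(df), spec$cols))
    stop_domain("%s: expected columns %s", path,
                paste(spec$cols, collapse = ", "))
  if (nrow(df) == 0L) stop_domain("%s: no data rows", path)
  required <- setdiff(spec$cols, "bpm")   # bpm may be NA (dropped estimate)
  bad <- which(rowSums(is.na(df[required])) > 0)
  if (length(bad) > 0L)
    stop_domain("%s: malformed row at line %d", path, bad[1] + 2L)
  if (anyNA(df$time_s) || any(diff(df$time_s) <= 0))
    stop_domain("%s: timestamps not strictly increasing at line %d", path,
                which(diff(df$time_s) <= 0)[1] + 3L)
  switch(kind,
    accel = {
      dt <- diff(df$time_s)
      if (max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt))
        stop_domain("%s: accelerometer sampling not uniform", path)
      accel_trace(df$accel_g, fs_hz = 1 / stats::median(dt),
                  t0 = df$time_s[1])
    },
    hr = hr_series(df$bpm,
                   sample_period_s = if (nrow(df) > 1L)
                     stats::median(diff(df$time_s)) else 5),
    gnss = gnss_track(df$time_s, df$lat_deg, df$lon_deg),
    power = {
      dt <- stats::median(diff(df$time_s))
      wingate_trial(df$power_w, fs_hz = 1 / dt,
                    duration_nominal_s = nrow(df) * dt)
    })
}

manifest_columns <- function() {
  c("athlete_id", "mass_kg", "height_cm", "age_y", "training_group",
    "session_date", "week_index", "session_id", "hr_file", "gnss_file",
    "wingate_pre_file", "wingate_post_file", "bosco_pre_file",
    "bosco_post_file")
}

#' Write a complete study directory
#'
#' Materializes a `study_dataset` (with traces) as a manifest CSV plus one
#' trace file per stream per session, the layout the readers consume.
#' Includes the questionnaire responses and the cohort configuration when
#' present.
#'
#' @param dataset a `study_dataset` whose sessions carry traces (simulate
#'   with `include_traces = TRUE`).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_study <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (length(dataset$sessions) == 0L) stop_domain("empty dataset")
  if (is.null(dataset$sessions[[1]]$traces))
    stop_domain("sessions carry no traces; simulate with include_traces = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ath <- dataset$athletes
  rows <- lapply(dataset$sessions, function(rec) {
    stem <- sprintf("%s_%s", rec$athlete_id, rec$session_id)
    files <- c(hr_file = paste0(stem, "_hr.csv"),
               gnss_file = paste0(stem, "_gnss.csv"),
               wingate_pre_file = paste0(stem, "_wingate_pre.csv"),
               wingate_post_file = paste0(stem, "_wingate_post.csv"),
               bosco_pre_file = paste0(stem, "_bosco_pre.csv"),
               bosco_post_file = paste0(stem, "_bosco_post.csv"))
    tr <- rec$traces
    write_trace_csv(tr$hr, file.path(dir, files[["hr_file"]]), "hr")
    write_trace_csv(tr$gnss, file.path(dir, files[["gnss_file"]]), "gnss")
    write_trace_csv(tr$wingate_pre,
                    file.path(dir, files[["wingate_pre_file"]]), "power")
    write_trace_csv(tr$wingate_post,
                    file.path(dir, files[["wingate_post_file"]]), "power")
    b_pre <- tr$bosco_pre; b_post <- tr$bosco_post
    write_trace_csv(if (inherits(b_pre, "accel_trace")) b_pre else b_pre$trace,
                    file.path(dir, files[["bosco_pre_file"]]), "accel")
    write_trace_csv(if (inherits(b_post, "accel_trace")) b_post
                    else b_post$trace,
                    file.path(dir, files[["bosco_post_file"]]), "accel")
    i <- match(rec$athlete_id, ath$athlete_id)
    data.frame(athlete_id = rec$athlete_id, mass_kg = ath$mass_kg[i],
               height_cm = ath$height_cm[i], age_y = ath$age_y[i],
               training_group = ath$training_group[i],
               session_date = rec$date %||% NA_character_,
               week_index = rec$week, session_id = rec$session_id,
               t(files), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$questionnaire))
    utils::write.csv(dataset$questionnaire,
                     file.path(dir, "questionnaire.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = dataset$seed, config_hash = config_hash(dataset$config)),
    file.path(dir, "study_metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study directory
#'
#' Loads the manifest and every referenced trace file into a
#' `study_dataset` (without scalar parameters; run [extract_parameters()]
#' next).
#'
#' @param dir study directory written by [write_study()] (or following the
#'   same layout).
#' @return A `study_dataset` with per-session traces.
#' @export
read_study <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stop_domain("no manifest.csv in %s", dir)
  mf <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(manifest_columns(), "session_id"),
                          names(mf))
  if (length(missing_cols) > 0L)
    stop_domain("manifest lacks columns: %s",
                paste(missing_cols, collapse = ", "))
  if (any(mf$week_index < 1L))
    stop_domain("week_index must be a positive integer")
  file_cols <- grep("_file$", names(mf), value = TRUE)
  for (fc in file_cols) {
    absent <- !file.exists(file.path(dir, mf[[fc]]))
    if (any(absent))
      stop_domain("referenced file missing: %s", mf[[fc]][which(absent)[1]])
  }
  athletes <- unique(mf[, c("athlete_id", "mass_kg", "height_cm", "age_y",
                            "training_group")])
  rownames(athletes) <- NULL
  sessions <- lapply(seq_len(nrow(mf)), function(i) {
    row <- mf[i, ]
    traces <- list(
      hr = read_trace_csv(file.path(dir, row$hr_file), "hr"),
      gnss = read_trace_csv(file.path(dir, row$gnss_file), "gnss"),
      wingate_pre = read_trace_csv(file.path(dir, row$wingate_pre_file),
                                   "power"),
      wingate_post = read_trace_csv(file.path(dir, row$wingate_post_file),
                                    "power"),
      bosco_pre = read_trace_csv(file.path(dir, row$bosco_pre_file), "accel"),
      bosco_post = read_trace_csv(file.path(dir, row$bosco_post_file),
                                  "accel"))
    structure(list(athlete_id = row$athlete_id, week = row$week_index,
                   session_id = row$session_id %||%
                     sprintf("W%dS%d", row$week_index, i),
                   date = row$session_date, scalars = NULL, traces = traces),
              class = "session_record")
  })
  q_path <- file.path(dir, "questionnaire.csv")
  questionnaire <- if (file.exists(q_path))
    utils::read.csv(q_path, stringsAsFactors = FALSE) else NULL
  structure(list(athletes = athletes, sessions = sessions, parameters = NULL,
                 config = NULL, seed = NA_integer_,
                 questionnaire = questionnaire, ground_truth = NULL),
            class = "study_dataset")
}

#' Small study configuration for fixtures and quick demonstrations
#'
#' Four athletes, three weeks of one session each, one-minute shuttle phases
#' and 8-second repeated-jump trials: every downstream stage runs in well
#' under a second while exercising both subgroups and all trace kinds.
#'
#' @param ... overrides forwarded to [cohort_config()].
#' @return A `cohort_config`.
#' @export
fixture_config <- function(...) {
  defaults <- list(n_athletes = 4L, n_weeks = 3L,
                   sessions_per_week = c(1L, 1L, 1L), nadir_week = 2L,
                   hr_weekly_bpm = c(155, 150, 145),
                   wingate_effect_by_week = c(0.90, 0.82, 0.93),
                   bosco_effect_by_week = c(0.93, 0.88, 0.96),
                   session_duration_min = 5,
                   phase_min = c(1, 1, 1, 1, 1),
                   bosco_duration_s = 8)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

#' Read a run configuration file (YAML or JSON)
#'
#' The file may contain top-level sections `cohort` (arguments of
#' [cohort_config()]), `analysis` (arguments of [analysis_config()]) and
#' `seed`. Unknown sections or keys are rejected.
#'
#' @param path configuration file; extension selects the parser
#'   (`.yaml`/`.yml` or `.json`).
#' @return List with `cohort` (a `cohort_config`), `analysis` (an
#'   `analysis_config`) and `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_domain("config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_domain("yaml package required for YAML configs; use JSON")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), c("cohort", "analysis", "seed"))
  if (length(unknown) > 0L)
    stop_domain("unknown config section(s): %s",
                paste(unknown, collapse = ", "))
  check_keys <- function(given, fn, where) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad) > 0L)
      stop_domain("unknown key(s) in `%s`: %s", where,
                  paste(bad, collapse = ", "))
  }
  ch <- raw$cohort %||% list()
  an <- raw$analysis %||% list()
  check_keys(ch, cohort_config, "cohort")
  check_keys(an, analysis_config, "analysis")
  list(cohort = do.call(cohort_config, ch),
       analysis = do.call(analysis_config, an),
       seed = as.integer(raw$seed %||% 1L))
}
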