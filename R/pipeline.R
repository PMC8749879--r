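## Study-level analysis pipeline: weekly grouping, pre/post comparisons,
## temporal trends with post hoc, subgroup descriptives, downfall/recovery
## phase detection and the full report bundle.

#' Parameter orientation table
#'
#' Whether a larger value of each monitored parameter means better
#' performance. Mean heart rate (higher = more strain for the same exercise)
#' and contact time (longer = slower rebound) are inverted; covered distance
#' is a protocol-reproducibility check and treated as neutral/larger-better.
#'
#' @return Named logical vector, `TRUE` = larger is better.
#' @export
parameter_orientation <- function() {
  c(hr_mean = FALSE, distance = TRUE,
    wingate_mean_power = TRUE, wingate_max_power = TRUE,
    bosco_h_max = TRUE, bosco_mean_power = TRUE, bosco_rsi = TRUE,
    bosco_stiffness = TRUE, bosco_tc = FALSE, bosco_tf = TRUE)
}

#' All monitored parameters
#' @return Character vector of the ten parameter names analysed by
#'   [build_report()].
#' @export
monitored_parameters <- function() names(parameter_orientation())

as_parameter_table <- function(dataset) {
  if (inherits(dataset, "study_dataset")) {
    if (is.null(dataset$parameters))
      stop_domain("dataset carries no parameter table; run extract_parameters()")
    dataset$parameters
  } else if (is.data.frame(dataset)) dataset
  else stop_domain("expected a study_dataset or a parameter data frame")
}

#' Aggregate sessions into one value per athlete-week
#'
#' Weeks with more than one acquisition contribute the arithmetic mean of
#' their sessions; single-session weeks pass through unchanged. Every
#' (athlete, week) pair must be covered by at least one session.
#'
#' @param dataset a `study_dataset` or tidy parameter data frame with
#'   columns `athlete_id`, `week`, `session_id`, `parameter`, `phase`,
#'   `value`.
#' @return Data frame with columns `athlete_id`, `week`, `parameter`,
#'   `phase`, `value` (one row per athlete-week-parameter-phase).
#' @export
weekly_group <- function(dataset) {
  pt <- as_parameter_table(dataset)
  need <- c("athlete_id", "week", "parameter", "phase", "value")
  if (!all(need %in% names(pt)))
    stop_domain("parameter table lacks columns: %s",
                paste(setdiff(need, names(pt)), collapse = ", "))
  cover <- unique(pt[, c("athlete_id", "week")])
  grid <- expand.grid(athlete_id = unique(pt$athlete_id),
                      week = sort(unique(pt$week)),
                      stringsAsFactors = FALSE)
  missing <- grid[!paste(grid$athlete_id, grid$week) %in%
                    paste(cover$athlete_id, cover$week), ]
  if (nrow(missing) > 0L)
    stop_domain("missing (athlete, week) cells: %s",
                paste(sprintf("(%s, w%d)", missing$athlete_id, missing$week),
                      collapse = ", "))
  agg <- stats::aggregate(value ~ athlete_id + week + parameter + phase,
                          data = pt, FUN = mean)
  agg[order(agg$parameter, agg$phase, agg$week, agg$athlete_id), ,
      drop = FALSE]
}

## athletes x weeks matrix of one parameter/phase from grouped data
week_matrix <- function(grouped, parameter, phase) {
  g <- grouped[grouped$parameter == parameter & grouped$phase == phase, ]
  if (nrow(g) == 0L)
    stop_domain("no values for parameter '%s' phase '%s'", parameter, phase)
  weeks <- sort(unique(g$week))
  ids <- sort(unique(g$athlete_id))
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(weeks),
              dimnames = list(ids, paste0("week", weeks)))
  m[cbind(match(g$athlete_id, ids), match(g$week, weeks))] <- g$value
  m
}

## athletes x weeks matrix of normalized variations for a pre/post parameter
nv_matrix <- function(grouped, parameter) {
  pre <- week_matrix(grouped, parameter, "pre")
  post <- week_matrix(grouped, parameter, "post")
  stopifnot(identical(dimnames(pre), dimnames(post)))
  m <- normalized_variation(pre, post)
  dimnames(m) <- dimnames(pre)
  m
}

#' Weekly pre-vs-post comparison of one parameter
#'
#' For each week: Wilcoxon signed-rank test of pre- vs post-effort values
#' across athletes, Cliff's delta of pre vs post (positive delta = pre
#' exceeds post, i.e. a fatigue-induced loss for larger-is-better
#' parameters), medians and IQRs of both phases, and a significance flag at
#' `cfg$alpha`.
#'
#' @param dataset a `study_dataset` or parameter data frame (pre/post
#'   parameter required).
#' @param parameter one of [monitored_parameters()] with pre/post phases.
#' @param cfg an [analysis_config()].
#' @return A data frame of class `weekly_table`, one row per week.
#' @export
prepost_analysis <- function(dataset, parameter, cfg = analysis_config()) {
  grouped <- weekly_group(dataset)
  pre <- week_matrix(grouped, parameter, "pre")
  post <- week_matrix(grouped, parameter, "post")
  weeks <- as.integer(sub("week", "", colnames(pre)))
  rows <- lapply(seq_along(weeks), function(j) {
    tr <- tryCatch(wilcoxon_signed_rank(pre[, j], post[, j], cfg),
                   error = function(e)
                     stop_domain("week %d, parameter %s: %s", weeks[j],
                                 parameter, conditionMessage(e)))
    es <- cliffs_delta(pre[, j], post[, j])
    mi_pre <- median_iqr(pre[, j], cfg)
    mi_post <- median_iqr(post[, j], cfg)
    data.frame(parameter = parameter, week = weeks[j],
               n = nrow(pre),
               pre_median = mi_pre$median, pre_iqr = mi_pre$iqr,
               post_median = mi_post$median, post_iqr = mi_post$iqr,
               statistic = tr$statistic, p_value = tr$p_value,
               exact = tr$exact, cliffs_delta = es$delta,
               significant = tr$p_value < cfg$alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("weekly_table", "data.frame")
  out
}

#' Temporal (week-by-week) trend analysis of one parameter
#'
#' Friedman test across weeks with Bonferroni post hoc pairs. Raw weekly
#' values enter the test for `hr_mean` and `distance`; performance
#' parameters (Wingate powers, Bosco outputs) are analysed on their
#' normalized variations, which removes inter-subject scale. Also returns
#' per-week medians/IQRs/CQVs of the analysed quantity for plotting.
#'
#' @inheritParams prepost_analysis
#' @param quantity override the raw-values/normalized-variations mapping:
#'   `"auto"` (default), `"raw"`, or `"nv"`.
#' @return A list of class `temporal_analysis` with elements `parameter`,
#'   `quantity` (`"raw"` or `"nv"`), `test` (Friedman `test_result`),
#'   `posthoc` (pairwise table), `weekly` (summary data frame) and `matrix`
#'   (athletes x weeks values analysed).
#' @export
temporal_analysis <- function(dataset, parameter, cfg = analysis_config(),
                              quantity = c("auto", "raw", "nv")) {
  quantity <- match.arg(quantity)
  if (quantity == "auto")
    quantity <- if (parameter %in% c("hr_mean", "distance")) "raw" else "nv"
  grouped <- weekly_group(dataset)
  m <- if (quantity == "raw") {
    phase <- if (parameter %in% c("hr_mean", "distance")) "session" else "pre"
    week_matrix(grouped, parameter, phase)
  } else nv_matrix(grouped, parameter)
  test <- friedman_rank_test(m)
  posthoc <- bonferroni_posthoc(m, cfg)
  weekly <- do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    mi <- median_iqr(m[, j], cfg)
    data.frame(parameter = parameter, quantity = quantity,
               week = as.integer(sub("week", "", colnames(m)[j])),
               median = mi$median, iqr = mi$iqr,
               cqv = if (all(m[, j] > 0)) cqv(m[, j], cfg) else NA_real_,
               n = nrow(m), stringsAsFactors = FALSE)
  }))
  structure(list(parameter = parameter, quantity = quantity, test = test,
                 posthoc = posthoc, weekly = weekly, matrix = m),
            class = "temporal_analysis")
}

#' @export
print.temporal_analysis <- function(x, ...) {
  cat(sprintf("<temporal_analysis> %s (%s values): Friedman Q = %.3f, p = %.4f\n",
              x$parameter, x$quantity, x$test$statistic, x$test$p_value))
  sig <- x$posthoc[x$posthoc$significant, , drop = FALSE]
  if (nrow(sig) > 0L)
    cat("  significant pairs:",
        paste(sprintf("%s-%s", sig$col_a, sig$col_b), collapse = ", "), "\n")
  invisible(x)
}

#' Subgroup descriptives by lockdown-training duration
#'
#' Splits athletes by `training_group` and reports per-group weekly medians
#' and IQRs of the analysed quantity (raw values for heart rate and
#' distance, normalized variations for performance parameters). Descriptive
#' only: no inferential test is run between subgroups.
#'
#' @inheritParams temporal_analysis
#' @param dataset a `study_dataset` (the athlete table supplies the groups).
#' @return Data frame: `parameter`, `quantity`, `training_group`, `week`,
#'   `median`, `iqr`, `n`.
#' @export
subgroup_analysis <- function(dataset, parameter, cfg = analysis_config(),
                              quantity = c("auto", "raw", "nv")) {
  if (!inherits(dataset, "study_dataset"))
    stop_domain("subgroup_analysis needs a study_dataset (athlete groups)")
  quantity <- match.arg(quantity)
  if (quantity == "auto")
    quantity <- if (parameter %in% c("hr_mean", "distance")) "raw" else "nv"
  grouped <- weekly_group(dataset)
  m <- if (quantity == "raw") {
    phase <- if (parameter %in% c("hr_mean", "distance")) "session" else "pre"
    week_matrix(grouped, parameter, phase)
  } else nv_matrix(grouped, parameter)
  groups <- dataset$athletes$training_group[
    match(rownames(m), dataset$athletes$athlete_id)]
  lvls <- unique(dataset$athletes$training_group)
  if (length(lvls) < 2L || any(!lvls %in% groups))
    stop_domain("both training subgroups must be non-empty")
  out <- do.call(rbind, lapply(lvls, function(g) {
    mg <- m[groups == g, , drop = FALSE]
    do.call(rbind, lapply(seq_len(ncol(mg)), function(j) {
      mi <- median_iqr(mg[, j], cfg)
      data.frame(parameter = parameter, quantity = quantity,
                 training_group = g,
                 week = as.integer(sub("week", "", colnames(mg)[j])),
                 median = mi$median, iqr = mi$iqr, n = nrow(mg),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Locate the nadir week and label downfall/recovery phases
#'
#' The nadir is the week of worst performance: the minimum of the weekly
#' medians for larger-is-better parameters, the maximum for inverted ones
#' (heart rate, contact time). Ties break toward the earlier week. Weeks up
#' to and including the nadir are labelled `"downfall"`, later weeks
#' `"recovery"`.
#'
#' @param weekly_medians ordered numeric vector of weekly medians (>= 3
#'   weeks).
#' @param larger_is_better orientation flag; see [parameter_orientation()].
#' @return List with `nadir_week` (1-based index) and `phases` (character
#'   vector of labels).
#' @examples
#' detect_phases(c(-8.5, -17.7, -2.0, -6.9))  # nadir at week 2
#' @export
detect_phases <- function(weekly_medians, larger_is_better = TRUE) {
  if (length(weekly_medians) < 3L)
    stop_domain("phase detection needs at least 3 weeks")
  nadir <- if (larger_is_better) which.min(weekly_medians)
  else which.max(weekly_medians)
  phases <- ifelse(seq_along(weekly_medians) <= nadir, "downfall", "recovery")
  list(nadir_week = as.integer(nadir), phases = phases)
}

#' Extract scalar parameters from raw session traces
#'
#' For datasets read from a study directory (or simulated with traces only),
#' computes the tidy parameter table: mean heart rate, haversine covered
#' distance, Wingate mean/peak powers and the six Bosco outputs (via jump
#' event detection and trial aggregation). Datasets that already carry a
#' parameter table are returned unchanged.
#'
#' @param dataset a `study_dataset`.
#' @param cfg an [analysis_config()] (quartile rule used downstream).
#' @param peak_window_s Wingate peak-power window, seconds.
#' @return The dataset with `parameters` filled in.
#' @export
extract_parameters <- function(dataset, cfg = analysis_config(),
                               peak_window_s = 1) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (!is.null(dataset$parameters)) return(dataset)
  mass <- stats::setNames(dataset$athletes$mass_kg,
                          dataset$athletes$athlete_id)
  recs <- lapply(dataset$sessions, function(rec) {
    tr <- rec$traces
    if (is.null(tr))
      stop_domain("session %s/%s has neither scalars nor traces",
                  rec$athlete_id, rec$session_id %||% "?")
    body <- body_params(mass[[rec$athlete_id]])
    sc <- list(hr_mean = mean_heart_rate(tr$hr),
               distance_m = total_distance(tr$gnss))
    for (phase in c("pre", "post")) {
      wp <- wingate_powers(tr[[paste0("wingate_", phase)]], peak_window_s)
      sc[[paste0("wingate_mean_power_", phase)]] <- wp$mean_power_w
      sc[[paste0("wingate_max_power_", phase)]] <- wp$max_power_w
      btr <- tr[[paste0("bosco_", phase)]]
      btrace <- if (inherits(btr, "accel_trace")) btr else btr$trace
      ev <- detect_jump_events(btrace)
      bs <- bosco_summary(ev, body)
      sc[[paste0("bosco_tc_", phase)]] <- bs$tc_s
      sc[[paste0("bosco_tf_", phase)]] <- bs$tf_s
      sc[[paste0("bosco_h_max_", phase)]] <- bs$h_max_m
      sc[[paste0("bosco_mean_power_", phase)]] <- bs$mean_power_w
      sc[[paste0("bosco_rsi_", phase)]] <- bs$rsi_ms
      sc[[paste0("bosco_stiffness_", phase)]] <- bs$stiffness_nm
    }
    rec$scalars <- sc
    rec
  })
  dataset$sessions <- recs
  dataset$parameters <- do.call(rbind, lapply(recs, session_parameter_rows))
  dataset
}

#' Run the full study analysis and write the report bundle
#'
#' For every monitored parameter: weekly pre/post comparison (Wilcoxon +
#' Cliff's delta; skipped for the two single-phase parameters), temporal
#' Friedman + Bonferroni post hoc, subgroup descriptives and
#' downfall/recovery phase detection. Writes tidy CSV tables, optional
#' per-parameter boxplot figures and a run-metadata JSON into `out_dir`.
#' Deterministic given dataset and configuration.
#'
#' @param dataset a `study_dataset` with parameters (run
#'   [extract_parameters()] first for trace-only data).
#' @param out_dir output directory, created if needed. `NULL` skips writing
#'   and returns the tables only.
#' @param cfg an [analysis_config()].
#' @param figures `"svg"` to write per-parameter boxplots, `"none"` to skip.
#' @return (Invisibly) a list of class `study_report`: `prepost`,
#'   `temporal_tests`, `posthoc`, `weekly_summaries`, `subgroups`, `phases`,
#'   `normality`, and `questionnaire` when the dataset carries responses.
#' @export
build_report <- function(dataset, out_dir = NULL, cfg = analysis_config(),
                         figures = c("none", "svg")) {
  figures <- match.arg(figures)
  stopifnot(inherits(dataset, "study_dataset"))
  if (length(dataset$sessions) == 0L)
    stop_domain("empty dataset: no sessions to analyse")
  dataset <- extract_parameters(dataset, cfg)
  params <- intersect(monitored_parameters(),
                      unique(dataset$parameters$parameter))
  orient <- parameter_orientation()

  prepost <- list(); temporal <- list(); posthoc <- list()
  weekly <- list(); subgrp <- list(); phases <- list(); normal <- list()
  for (p in params) {
    has_prepost <- !p %in% c("hr_mean", "distance")
    if (has_prepost)
      prepost[[p]] <- prepost_analysis(dataset, p, cfg)
    ta <- temporal_analysis(dataset, p, cfg)
    temporal[[p]] <- data.frame(parameter = p, quantity = ta$quantity,
                                statistic = ta$test$statistic,
                                p_value = ta$test$p_value,
                                significant = ta$test$p_value < cfg$alpha,
                                stringsAsFactors = FALSE)
    ph <- ta$posthoc
    ph$parameter <- p
    posthoc[[p]] <- ph
    weekly[[p]] <- ta$weekly
    subgrp[[p]] <- subgroup_analysis(dataset, p, cfg)
    det <- detect_phases(ta$weekly$median[order(ta$weekly$week)],
                         larger_is_better = isTRUE(orient[[p]]))
    phases[[p]] <- data.frame(parameter = p, quantity = ta$quantity,
                              nadir_week = det$nadir_week,
                              phases = paste(det$phases, collapse = ","),
                              stringsAsFactors = FALSE)
    ks <- ks_normality(as.vector(ta$matrix), cfg)
    normal[[p]] <- data.frame(parameter = p, quantity = ta$quantity,
                              D = ks$statistic, p_value = ks$p_value,
                              normal_rejected = ks$p_value < cfg$alpha,
                              stringsAsFactors = FALSE)
  }
  report <- list(prepost = do.call(rbind, unname(prepost)),
                 temporal_tests = do.call(rbind, unname(temporal)),
                 posthoc = do.call(rbind, unname(posthoc)),
                 weekly_summaries = do.call(rbind, unname(weekly)),
                 subgroups = do.call(rbind, unname(subgrp)),
                 phases = do.call(rbind, unname(phases)),
                 normality = do.call(rbind, unname(normal)))
  if (!is.null(dataset$questionnaire))
    report$questionnaire <- questionnaire_summary(dataset$questionnaire)
  class(report) <- "study_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(report), "class"))
      utils::write.csv(report[[nm]],
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    meta <- list(package = "rebound",
                 version = as.character(utils::packageVersion("rebound")),
                 seed = dataset$seed,
                 alpha = cfg$alpha,
                 config_hash = config_hash(dataset$config),
                 n_athletes = nrow(dataset$athletes),
                 n_sessions = length(dataset$sessions),
                 parameters = params)
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (figures == "svg")
      write_report_figures(dataset, report, out_dir, cfg)
  }
  invisible(report)
}

## weekly boxplots of the analysed quantity, one SVG per parameter
write_report_figures <- function(dataset, report, out_dir, cfg) {
  if (!capabilities("cairo")) {
    message("svg device unavailable; skipping figures")
    return(invisible(NULL))
  }
  grouped <- weekly_group(dataset)
  for (p in unique(report$weekly_summaries$parameter)) {
    q <- report$weekly_summaries$quantity[
      report$weekly_summaries$parameter == p][1]
    m <- if (q == "raw") {
      phase <- if (p %in% c("hr_mean", "distance")) "session" else "pre"
      week_matrix(grouped, p, phase)
    } else nv_matrix(grouped, p)
    df <- data.frame(week = factor(rep(sub("week", "", colnames(m)),
                                       each = nrow(m))),
                     value = as.vector(m))
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = week, y = value)) +
      ggplot2::geom_boxplot(fill = "grey85") +
      ggplot2::labs(title = p,
                    y = if (q == "nv") "normalized variation (%)" else p,
                    x = "week") +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, paste0("fig_", p, ".svg"))
    grDevices::svg(f, width = 5, height = 4)
    print(gg)
    grDevices::dev.off()
  }
  invisible(NULL)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d parameters; %d pre/post rows, %d post hoc pairs\n",
              length(unique(x$weekly_summaries$parameter)),
              if (is.null(x$prepost)) 0L else nrow(x$prepost),
              nrow(x$posthoc)))
  invisible(x)
}

## short stable hash of a configuration (FNV-1a over its deparsed form)
config_hash <- function(cfg) {
  s <- paste(deparse(cfg, control = "all"), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # xor touches the low byte only
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
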