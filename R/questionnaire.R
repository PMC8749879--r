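## Lockdown-training questionnaire: item schema, descriptive summary and a
## deterministic synthetic response set for testing.

#' Questionnaire item schema
#'
#' The short survey on self-administered training during the forced-rest
#' period: yes/no items, frequency and duration categories, 1--10 intensity
#' scores, and pre/post-lockdown habit items.
#'
#' @return A named list; each element has `text`, `type`
#'   (`"yes_no"`, `"category"` or `"numeric"`) and, for categorical items,
#'   `options`.
#' @export
questionnaire_items <- function() {
  freq <- c("Daily", "Every alternate day", "2 times a week", "Once a week")
  habit <- c("Several times a week", "Once a week", "Rarely", "No")
  list(
    self_training = list(
      text = "Did you carry out self-administered training sessions during the lockdown?",
      type = "yes_no", options = c("Yes", "No")),
    aerobic = list(
      text = "Did you carry out aerobic/cardio exercises?",
      type = "yes_no", options = c("Yes", "No")),
    aerobic_freq = list(
      text = "How often did you do aerobic/cardio training in a week?",
      type = "category", options = freq),
    aerobic_intensity = list(
      text = "How intense was your aerobic/cardio training (1-10)?",
      type = "numeric"),
    strength = list(
      text = "Did you carry out muscular strength training?",
      type = "yes_no", options = c("Yes", "No")),
    strength_freq = list(
      text = "How often did you do strength training exercises in a week?",
      type = "category", options = freq),
    strength_intensity = list(
      text = "How intense was your strength training (1-10)?",
      type = "numeric"),
    workout_duration = list(
      text = "During the lockdown, what was the overall duration of your workouts?",
      type = "category",
      options = c("<30 min", "30-45 min", "45-60 min", ">60 min")),
    pre_lockdown_extra = list(
      text = "Before the lockdown, were you used to perform training in addition to team training?",
      type = "category", options = habit),
    post_lockdown_extra = list(
      text = "After the lockdown, have you continued additional self-administered sessions?",
      type = "category", options = habit))
}

#' Descriptive summary of questionnaire responses
#'
#' Counts and percentages of respondents per option for categorical items
#' (percentages of non-missing responses, rounded to whole percent), mean
#' and standard deviation for numeric items.
#'
#' @param responses data frame with one row per athlete; columns
#'   `athlete_id` plus one column per item of [questionnaire_items()].
#'   Missing answers (`NA`) are allowed (e.g. intensity of a training type
#'   the athlete did not practise).
#' @return Long data frame: `item`, `option`, `count`, `percent`, `mean`,
#'   `sd` (the last two filled only for numeric items).
#' @examples
#' questionnaire_summary(simulate_questionnaire())
#' @export
questionnaire_summary <- function(responses) {
  stopifnot(is.data.frame(responses))
  if (nrow(responses) == 0L) stop_domain("no questionnaire responses")
  items <- questionnaire_items()
  rows <- list()
  for (nm in names(items)) {
    it <- items[[nm]]
    if (!nm %in% names(responses)) next
    ans <- responses[[nm]]
    if (it$type == "numeric") {
      v <- ans[!is.na(ans)]
      rows[[nm]] <- data.frame(item = nm, option = NA_character_,
                               count = length(v), percent = NA_real_,
                               mean = mean(v), sd = stats::sd(v),
                               stringsAsFactors = FALSE)
    } else {
      v <- ans[!is.na(ans)]
      bad <- setdiff(unique(v), it$options)
      if (length(bad) > 0L)
        stop_domain("unknown option '%s' for item '%s'", bad[1], nm)
      cnt <- table(factor(v, levels = it$options))
      rows[[nm]] <- data.frame(item = nm, option = names(cnt),
                               count = as.integer(cnt),
                               percent = round(100 * as.integer(cnt) /
                                                 length(v)),
                               mean = NA_real_, sd = NA_real_,
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}

#' Deterministic synthetic questionnaire responses
#'
#' Eight synthetic athletes whose marginal tallies follow the pattern typical
#' of a post-lockdown cohort: all trained on their own, most did aerobic
#' work, three quarters did strength training, and workout durations split
#' the cohort into the "<45min" and ">=45min" training subgroups (four
#' athletes each).
#'
#' @param athlete_ids character vector of 8 athlete ids.
#' @return Data frame of responses, one row per athlete.
#' @export
simulate_questionnaire <- function(athlete_ids = sprintf("A%02d", 1:8)) {
  if (length(athlete_ids) != 8L)
    stop_domain("the synthetic questionnaire is defined for 8 athletes")
  data.frame(
    athlete_id = athlete_ids,
    self_training = rep("Yes", 8),
    aerobic = c(rep("Yes", 7), "No"),
    aerobic_freq = c(rep("Every alternate day", 3),
                     rep("2 times a week", 4), NA),
    aerobic_intensity = c(5, 6, 6, 6, 7, 7, 8, NA),
    strength = c(rep("Yes", 6), "No", "No"),
    strength_freq = c("Daily", "Every alternate day", "Every alternate day",
                      "2 times a week", "2 times a week", "Once a week",
                      NA, NA),
    strength_intensity = c(6, 6, 7, 7, 7, 8, NA, NA),
    workout_duration = c("<30 min", "30-45 min", "30-45 min", "30-45 min",
                         "45-60 min", "45-60 min", "45-60 min", ">60 min"),
    pre_lockdown_extra = c(rep("Rarely", 4), rep("No", 4)),
    post_lockdown_extra = c(rep("Several times a week", 3),
                            rep("Once a week", 2), rep("Rarely", 2), "No"),
    stringsAsFactors = FALSE)
}
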