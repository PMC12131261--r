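# Composite facial-expression-processing score: per-trial raw scores,
# z-standardisation within trial type, per-subject aggregation.

#' Assemble trial-level raw scores from the three experiments
#'
#' Converts each experiment's includable-trial results to the raw score that
#' feeds the composite: paired expression trials contribute the absolute
#' attention bias `|bias_p - 0.5|` (bias toward and away from the expression
#' count equally), intensity trials contribute the attention bias itself,
#' and sequence trials contribute the binary exceeds-prediction response.
#' Trial types are the Exp1 expression (three types), the Exp2 intensity
#' level (four types), and a single Exp3 type.
#'
#' @param exp1_records Output of [add_attention_bias()] on expression trials
#'   (needs `expression`), or `NULL`.
#' @param exp2_records Output of [add_attention_bias()] on intensity trials
#'   (needs `intensity`), or `NULL`.
#' @param exp3_records Output of [violation_records()], or `NULL`.
#' @return Tibble: `subject_id`, `experiment`, `trial_type`, `raw`.
#' @export
trial_scores <- function(exp1_records = NULL, exp2_records = NULL,
                         exp3_records = NULL) {
  parts <- list()
  if (!is.null(exp1_records) && nrow(exp1_records) > 0) {
    check_columns(exp1_records, c("subject_id", "expression", "bias_p"),
                  "Exp1 records")
    parts$exp1 <- tibble(
      subject_id = exp1_records$subject_id,
      experiment = "exp1",
      trial_type = paste0("exp1_", exp1_records$expression),
      raw = abs(exp1_records$bias_p - 0.5)
    )
  }
  if (!is.null(exp2_records) && nrow(exp2_records) > 0) {
    check_columns(exp2_records, c("subject_id", "intensity", "bias_p"),
                  "Exp2 records")
    parts$exp2 <- tibble(
      subject_id = exp2_records$subject_id,
      experiment = "exp2",
      trial_type = sprintf("exp2_%03d", round(100 * exp2_records$intensity)),
      raw = exp2_records$bias_p
    )
  }
  if (!is.null(exp3_records) && nrow(exp3_records) > 0) {
    check_columns(exp3_records, c("subject_id", "exceeds"), "Exp3 records")
    parts$exp3 <- tibble(
      subject_id = exp3_records$subject_id,
      experiment = "exp3",
      trial_type = "exp3",
      raw = as.numeric(exp3_records$exceeds)
    )
  }
  if (length(parts) == 0) {
    return(tibble(subject_id = character(), experiment = character(),
                  trial_type = character(), raw = numeric()))
  }
  dplyr::bind_rows(parts)
}

#' Standardise raw scores within trial type
#'
#' Adds `z = (raw - mean) / sd` per trial type, using the sample (n - 1)
#' standard deviation over all trials of that type pooled across subjects.
#' Trial types with fewer than two trials or zero variance cannot be
#' standardised; they are dropped with a warning and their trials do not
#' contribute to composites.
#'
#' @param scores Tibble from [trial_scores()].
#' @return `scores` with a `z` column, minus any dropped trial types.
#' @export
standardize_trial_scores <- function(scores) {
  check_columns(scores, c("subject_id", "trial_type", "raw"), "Trial scores")
  scores <- as_tibble(scores)
  stats <- scores |>
    dplyr::group_by(.data$trial_type) |>
    dplyr::summarise(m = mean(.data$raw), s = sd(.data$raw), n = dplyr::n())
  bad <- stats$trial_type[stats$n < 2 | is.na(stats$s) | stats$s == 0]
  if (length(bad) > 0) {
    warn(sprintf(
      "Dropping trial type(s) with <2 trials or zero variance: %s",
      paste(bad, collapse = ", ")
    ))
    scores <- scores[!scores$trial_type %in% bad, , drop = FALSE]
    stats <- stats[!stats$trial_type %in% bad, , drop = FALSE]
  }
  scores |>
    dplyr::left_join(stats[c("trial_type", "m", "s")], by = "trial_type") |>
    dplyr::mutate(z = (.data$raw - .data$m) / .data$s) |>
    dplyr::select(-"m", -"s")
}

#' Per-subject composite facial-expression-processing scores
#'
#' Averages each subject's standardised scores within trial type, then
#' averages those type means across the subject's trial types (the default),
#' or averages straight across all of the subject's trials
#' (`aggregate = "trials"`). Subjects contributing fewer than `min_trials`
#' trials in total (across all experiments) are omitted.
#'
#' @param scores Standardised scores from [standardize_trial_scores()].
#' @param min_trials Minimum total trials per subject (default 3).
#' @param aggregate `"type_means"` (default) or `"trials"`.
#' @return Tibble: `subject_id`, `score`, `n_trials`, `n_types`.
#' @export
composite_scores <- function(scores, min_trials = 3,
                             aggregate = c("type_means", "trials")) {
  aggregate <- match.arg(aggregate)
  check_columns(scores, c("subject_id", "trial_type", "z"), "Standardised scores")
  per_subject <- scores |>
    dplyr::group_by(.data$subject_id, .data$trial_type) |>
    dplyr::summarise(type_mean = mean(.data$z), n = dplyr::n(), .groups = "drop_last") |>
    dplyr::summarise(
      score_types = mean(.data$type_mean),
      score_trials = sum(.data$type_mean * .data$n) / sum(.data$n),
      n_trials = sum(.data$n),
      n_types = dplyr::n(),
      .groups = "drop"
    )
  omitted <- per_subject$subject_id[per_subject$n_trials < min_trials]
  if (length(omitted) > 0) {
    message(length(omitted), " subject(s) omitted with fewer than ",
            min_trials, " trials")
  }
  out <- per_subject[per_subject$n_trials >= min_trials, , drop = FALSE]
  out$score <- if (aggregate == "type_means") out$score_types else out$score_trials
  out[c("subject_id", "score", "n_trials", "n_types")]
}
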