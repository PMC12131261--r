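# End-to-end convenience wrapper over the analysis stages.

#' Composite scores straight from a study's trial tables
#'
#' Runs inclusion filtering, attention-bias and violation scoring, trial-type
#' z-standardisation and per-subject aggregation in one call.
#'
#' @param study An `fb_study` (generated or read from disk).
#' @param min_trials Minimum total trials per subject (default 3).
#' @return Tibble from [composite_scores()].
#' @export
study_composite <- function(study, min_trials = 3) {
  e1 <- add_attention_bias(apply_inclusion(study$exp1)$included)
  e2 <- add_attention_bias(apply_inclusion(study$exp2)$included)
  e3 <- violation_records(apply_inclusion(study$exp3)$included)
  scores <- standardize_trial_scores(trial_scores(e1, e2, e3))
  composite_scores(scores, min_trials = min_trials)
}

#' Run the full analysis pipeline on a study
#'
#' Applies the inclusion criteria, computes per-trial attention biases and
#' violation records, the population-level statistics (per-expression
#' t-tests against 0.5, expression and intensity mixed models,
#' Tukey-adjusted expression contrasts, the paired violation test), the
#' composite scores, and — when subjects and maternal data are available —
#' the maternal-care model and the age follow-up suite.
#'
#' @param study An `fb_study`.
#' @param min_trials Minimum total trials per subject for a composite score.
#' @return A list with `exp1` (records, tests, model, contrasts), `exp2`
#'   (records, model), `exp3` (records, test), `composite`, and, if
#'   estimable, `maternal_model` and `age_models`.
#' @export
analyze_study <- function(study, min_trials = 3) {
  e1 <- add_attention_bias(apply_inclusion(study$exp1)$included)
  e2 <- add_attention_bias(apply_inclusion(study$exp2)$included)
  e3 <- violation_records(apply_inclusion(study$exp3)$included)

  out <- list(
    exp1 = list(
      records = e1,
      tests = attention_bias_tests(e1),
      model = fit_expression_lmm(e1)
    ),
    exp2 = list(records = e2, model = fit_intensity_lmm(e2)),
    exp3 = list(records = e3, test = violation_test(e3))
  )
  out$exp1$contrasts <- expression_contrasts(out$exp1$model)

  scores <- standardize_trial_scores(trial_scores(e1, e2, e3))
  out$composite <- composite_scores(scores, min_trials = min_trials)

  if (!is.null(study$maternal) && nrow(study$maternal) >= 8) {
    with_mat <- sum(out$composite$subject_id %in% study$maternal$subject_id)
    if (with_mat >= 8) {
      out$maternal_model <- fit_maternal_model(
        out$composite, study$subjects, study$maternal
      )
    }
  }
  if (!is.null(study$subjects) && nrow(out$composite) >= 10 &&
      length(unique(study$subjects$age_years)) >= 3) {
    ages <- dplyr::inner_join(out$composite, study$subjects, by = "subject_id")
    if (nlevels(droplevels(factor(ages$age_group))) == 2) {
      out$age_models <- fit_age_models(out$composite, study$subjects)
    }
  }
  out
}
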