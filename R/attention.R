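# Attention-bias analysis: per-trial looking proportions, one-sample tests
# against indifference, and the expression / intensity mixed models.

#' Add per-trial attention-bias proportions
#'
#' The attention bias of a paired trial is the time spent looking at the
#' expression as a proportion of the total time spent looking at both
#' images. Defined only for includable trials (both looking times positive);
#' non-includable trials are dropped.
#'
#' @param trials Paired-trial tibble (`look_expression_s`, `look_neutral_s`,
#'   `includable`).
#' @return The includable trials with a `bias_p` column in `[0, 1]`.
#' @examples
#' tr <- tibble::tibble(look_expression_s = 3.2, look_neutral_s = 1.8,
#'                      includable = TRUE)
#' add_attention_bias(tr)$bias_p # 0.64
#' @export
add_attention_bias <- function(trials) {
  check_columns(trials, c("look_expression_s", "look_neutral_s", "includable"),
                "Paired trials")
  out <- dplyr::filter(as_tibble(trials), .data$includable)
  denom <- out$look_expression_s + out$look_neutral_s
  if (any(out$look_expression_s <= 0 | out$look_neutral_s <= 0)) {
    stop_input(
      "Trial flagged includable has a non-positive looking time; run apply_inclusion() first",
      class = "facebias_error_precondition"
    )
  }
  out$bias_p <- out$look_expression_s / denom
  out
}

#' One-sample t-test of attention bias against indifference
#'
#' Tests whether a set of per-trial looking proportions differs from 0.5,
#' i.e. whether there is an attention bias toward (mean > 0.5) or away from
#' (mean < 0.5) the expression. Two-sided, df = n - 1.
#'
#' @param bias_p Numeric vector of per-trial looking proportions.
#' @param null_value Proportion under no bias (0.5).
#' @return One-row tibble: `estimate` (sample mean), `statistic` (t), `df`,
#'   `p.value`, `conf.low`, `conf.high`, `null.value`, `n`.
#' @examples
#' test_bias_vs_half(c(0.6, 0.7, 0.5, 0.6)) # t = 2.449, df = 3
#' @export
test_bias_vs_half <- function(bias_p, null_value = 0.5) {
  bias_p <- bias_p[!is.na(bias_p)]
  if (length(bias_p) < 2) {
    stop_input("Need at least 2 bias values for a t-test",
               class = "facebias_error_degenerate")
  }
  if (sd(bias_p) == 0) {
    stop_input("Bias values are constant; the t statistic is undefined",
               class = "facebias_error_degenerate")
  }
  tt <- t.test(bias_p, mu = null_value)
  tibble(
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    conf.low = tt$conf.int[1],
    conf.high = tt$conf.int[2],
    null.value = null_value,
    n = length(bias_p)
  )
}

#' Per-expression attention-bias tests
#'
#' Convenience wrapper running [test_bias_vs_half()] within each expression
#' type of a paired-trial table.
#'
#' @param records Output of [add_attention_bias()] with an `expression`
#'   column.
#' @return Tibble with one test row per expression.
#' @export
attention_bias_tests <- function(records) {
  check_columns(records, c("expression", "bias_p"), "Bias records")
  records |>
    dplyr::group_by(.data$expression) |>
    dplyr::group_modify(~ test_bias_vs_half(.x$bias_p)) |>
    dplyr::ungroup()
}

fit_fb_lmm <- function(formula, data, REML = TRUE, scale_note = NULL) {
  fit <- lmerTest::lmer(formula, data = data, REML = REML)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warn("Mixed-model fit is singular (a random-effect variance is zero); reported, not dropped")
  }
  smry <- summary(fit, ddf = "Satterthwaite")
  ct <- as.data.frame(smry$coefficients)
  coef_tbl <- tibble(
    term = rownames(ct),
    estimate = ct[["Estimate"]],
    std.error = ct[["Std. Error"]],
    df = ct[["df"]],
    statistic = ct[["t value"]],
    p.value = ct[["Pr(>|t|)"]]
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      fit = fit,
      coefficients = coef_tbl,
      varcor = tibble(
        group = vc$grp, term = vc$var1, variance = vc$vcov, sd = vc$sdcor
      ),
      REML = REML,
      singular = singular,
      formula = formula,
      nobs = nrow(data),
      scale_note = scale_note
    ),
    class = "fb_lmm"
  )
}

#' Mixed model of attention bias on expression type
#'
#' Fits `bias_p ~ expression + (1 | group_id / subject_id)`: fixed effect of
#' expression type, random intercepts for social group and for subject
#' nested within group, REML by default, Satterthwaite denominator df.
#' Singular fits are flagged in the result, never silently simplified.
#'
#' @param records Bias records with `bias_p`, `expression`, `group_id`,
#'   `subject_id`.
#' @param REML Use REML (default) or ML.
#' @return An object of class `fb_lmm`; see [tidy.fb_lmm()] and
#'   [glance.fb_lmm()].
#' @export
fit_expression_lmm <- function(records, REML = TRUE) {
  check_columns(records, c("bias_p", "expression", "group_id", "subject_id"),
                "Bias records")
  if (length(unique(records$expression)) < 2) {
    stop_input("Need at least 2 expression levels", class = "facebias_error_degenerate")
  }
  records$expression <- factor(records$expression)
  fit_fb_lmm(
    bias_p ~ expression + (1 | group_id / subject_id),
    data = as_tibble(records), REML = REML,
    scale_note = "bias_p is a proportion in [0, 1], untransformed"
  )
}

#' Tukey-adjusted pairwise contrasts of expression marginal means
#'
#' Pairwise differences of the estimated marginal means of the expression
#' levels from a fitted [fit_expression_lmm()] model, with Tukey-adjusted
#' p-values.
#'
#' @param model An `fb_lmm` from [fit_expression_lmm()].
#' @param adjust Multiplicity adjustment (default `"tukey"`).
#' @return Tibble: `contrast`, `estimate`, `std.error`, `df`, `statistic`,
#'   `p.value`.
#' @export
expression_contrasts <- function(model, adjust = "tukey") {
  if (!inherits(model, "fb_lmm")) stop_input("`model` must be an fb_lmm")
  if (!any(grepl("^expression", model$coefficients$term))) {
    stop_input("Model has no expression factor", class = "facebias_error_input")
  }
  emm <- emmeans::emmeans(model$fit, ~expression, lmer.df = "satterthwaite")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = adjust))
  tibble(
    contrast = as.character(prs$contrast),
    estimate = prs$estimate,
    std.error = prs$SE,
    df = prs$df,
    statistic = prs$t.ratio,
    p.value = prs$p.value
  )
}

#' Mixed model of attention bias on threat intensity
#'
#' Fits `bias_p ~ intensity + (1 | group_id / subject_id)` with intensity as
#' a continuous numeric predictor on the 0.25-1 proportion scale (the scale
#' is recorded in the result metadata because it changes the slope's
#' magnitude).
#'
#' @param records Bias records with `bias_p`, `intensity`, `group_id`,
#'   `subject_id`.
#' @param REML Use REML (default) or ML.
#' @return An object of class `fb_lmm`.
#' @export
fit_intensity_lmm <- function(records, REML = TRUE) {
  check_columns(records, c("bias_p", "intensity", "group_id", "subject_id"),
                "Bias records")
  if (length(unique(records$intensity)) < 2) {
    stop_input("Need at least 2 intensity values", class = "facebias_error_degenerate")
  }
  fit_fb_lmm(
    bias_p ~ intensity + (1 | group_id / subject_id),
    data = as_tibble(records), REML = REML,
    scale_note = "intensity on the 0.25-1 proportion scale"
  )
}
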