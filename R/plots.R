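# ggplot2 figures for each result type.

#' Attention bias by expression type
#'
#' Per-trial looking proportions by expression with the indifference line at
#' 0.5; points above the line looked longer at the expression than at the
#' neutral face.
#'
#' @param records Output of [add_attention_bias()] with `expression`.
#' @return A ggplot.
#' @export
plot_attention_bias <- function(records) {
  check_columns(records, c("expression", "bias_p"), "Bias records")
  ggplot2::ggplot(records, ggplot2::aes(x = .data$expression, y = .data$bias_p)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, colour = "firebrick") +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, colour = "black") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "Expression", y = "Proportion of looking at expression") +
    ggplot2::theme_minimal()
}

#' Attention bias against threat intensity
#'
#' Per-trial looking proportions against intensity, with the fitted
#' fixed-effect line from an intensity model if supplied.
#'
#' @param records Output of [add_attention_bias()] with `intensity`.
#' @param model Optional `fb_lmm` from [fit_intensity_lmm()].
#' @return A ggplot.
#' @export
plot_intensity_bias <- function(records, model = NULL) {
  check_columns(records, c("intensity", "bias_p"), "Bias records")
  p <- ggplot2::ggplot(records, ggplot2::aes(x = .data$intensity, y = .data$bias_p)) +
    ggplot2::geom_jitter(width = 0.02, alpha = 0.4, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "Threat intensity", y = "Proportion of looking at expression") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    ct <- model$coefficients
    b0 <- ct$estimate[ct$term == "(Intercept)"]
    b1 <- ct$estimate[ct$term == "intensity"]
    p <- p + ggplot2::geom_abline(intercept = b0, slope = b1, colour = "black")
  }
  p
}

#' Looking time by image position in violation sequences
#'
#' Mean looking time (with standard errors) at each image position; the
#' sixth image violates the expression sequence.
#'
#' @param trials Sequence-trial tibble with `look_1` ... `look_6`.
#' @return A ggplot.
#' @export
plot_violation <- function(trials) {
  check_columns(trials, paste0("look_", 1:6), "Sequence trials")
  long <- tidyr::pivot_longer(
    trials[paste0("look_", 1:6)],
    cols = dplyr::everything(), names_to = "position",
    names_prefix = "look_", values_to = "look_s"
  )
  long$position <- as.integer(long$position)
  long <- long[!is.na(long$look_s), ]
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$position), y = .data$look_s)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, colour = "firebrick") +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, colour = "black") +
    ggplot2::labs(x = "Image position (6 violates the sequence)",
                  y = "Looking time (s)") +
    ggplot2::theme_minimal()
}

#' Composite score across age by age group
#'
#' Composite facial-expression-processing score against age with separate
#' linear trends for juveniles (under the cutoff) and adults.
#'
#' @param composite Tibble from [composite_scores()].
#' @param subjects Subject table with `age_years`.
#' @param cutoff Juvenile/adult age cutoff in years (default 5).
#' @return A ggplot.
#' @export
plot_age_trajectory <- function(composite, subjects, cutoff = 5) {
  dat <- dplyr::inner_join(composite, as_tibble(subjects), by = "subject_id")
  dat$age_group <- ifelse(dat$age_years < cutoff, "juvenile", "adult")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$age_years, y = .data$score,
                                    colour = .data$age_group)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "Age (years)", y = "Composite score", colour = "Age group") +
    ggplot2::theme_minimal()
}
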