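# Individual-differences models: maternal-care mixed model and the age
# follow-up suite on composite scores.

#' Orthonormal polynomial basis
#'
#' Orthogonal-polynomial columns of the requested degree: mutually
#' orthogonal, unit norm, orthogonal to the constant — the coding behind
#' `poly(age, 2)` coefficients in linear-model coefficient tables. Delegates
#' to [stats::poly()] after validating that enough distinct values exist.
#'
#' @param values Numeric vector (e.g. ages in years).
#' @param degree Polynomial degree (default 2).
#' @return A numeric matrix with `degree` columns.
#' @examples
#' ortho_poly(c(1, 2, 3), 2) # linear column (-1, 0, 1)/sqrt(2)
#' @export
ortho_poly <- function(values, degree = 2) {
  if (anyNA(values)) stop_input("`values` must not contain NA")
  if (length(unique(values)) < degree + 1) {
    stop_input(sprintf(
      "Need at least %d distinct values for a degree-%d orthogonal polynomial",
      degree + 1, degree
    ), class = "facebias_error_degenerate")
  }
  unclass(stats::poly(values, degree = degree))[, , drop = FALSE]
}

#' Maternal-care mixed model on composite scores
#'
#' Fits the individual-differences model on subjects with maternal records:
#' `score ~ grooming_score + cradling_score + approach_count +
#' restrain_count + sex + poly(age_years, 2)`, with crossed random
#' intercepts for social group and mother, REML, Satterthwaite df. Grooming
#' and cradling enter as proportions of scans in `[0, 1]`; approaches and
#' restraints as counts over the observation battery (the scaling is
#' recorded in the result metadata).
#'
#' @param composite Tibble from [composite_scores()].
#' @param subjects Subject table (`subject_id`, `sex`, `age_years`,
#'   `group_id`, `mother_id`).
#' @param maternal Maternal table (`subject_id`, `grooming_score`,
#'   `cradling_score`, `approach_count`, `restrain_count`).
#' @param REML Use REML (default) or ML.
#' @return An object of class `fb_lmm`.
#' @export
fit_maternal_model <- function(composite, subjects, maternal, REML = TRUE) {
  check_columns(composite, c("subject_id", "score"), "Composite scores")
  check_columns(subjects, c("subject_id", "sex", "age_years", "group_id", "mother_id"),
                "Subjects")
  check_columns(maternal,
                c("subject_id", "grooming_score", "cradling_score",
                  "approach_count", "restrain_count"),
                "Maternal records")
  dat <- composite |>
    dplyr::inner_join(as_tibble(subjects), by = "subject_id") |>
    dplyr::inner_join(as_tibble(maternal), by = "subject_id")
  if (nrow(dat) < 8) {
    stop_input("Too few subjects with both composite scores and maternal data",
               class = "facebias_error_degenerate")
  }
  if (length(unique(dat$age_years)) < 3) {
    stop_input("Need at least 3 distinct ages for the quadratic age term",
               class = "facebias_error_degenerate")
  }
  fit_fb_lmm(
    score ~ grooming_score + cradling_score + approach_count + restrain_count +
      sex + poly(age_years, 2) + (1 | group_id) + (1 | mother_id),
    data = dat, REML = REML,
    scale_note = paste(
      "grooming/cradling are proportions of scans in [0,1];",
      "approach/restrain are counts per nine-focal battery"
    )
  )
}

#' Age follow-up model suite on composite scores
#'
#' Fits the four age models used in the larger-sample follow-up, each with
#' composite score as the response, sex as a fixed effect and a random
#' intercept for group: (1) linear age, (2) log(age), (3) orthogonal
#' quadratic age, and (4) continuous age crossed with the juvenile/adult
#' category (cutoff: juvenile strictly under 5 years), parameterised so each
#' age stratum gets its own slope.
#'
#' @param composite Tibble from [composite_scores()].
#' @param subjects Subject table (`subject_id`, `sex`, `age_years`,
#'   `group_id`).
#' @param cutoff Age in years separating juveniles from adults (default 5).
#' @param REML Use REML (default) or ML.
#' @return A named list of class `fb_age_suite` with elements `linear_age`,
#'   `log_age`, `poly_age`, `age_by_group_interaction` (each an `fb_lmm`).
#' @export
fit_age_models <- function(composite, subjects, cutoff = 5, REML = TRUE) {
  check_columns(composite, c("subject_id", "score"), "Composite scores")
  check_columns(subjects, c("subject_id", "sex", "age_years", "group_id"),
                "Subjects")
  dat <- dplyr::inner_join(composite, as_tibble(subjects), by = "subject_id")
  if (length(unique(dat$age_years)) < 2) {
    stop_input("Ages are constant; age effects are undefined",
               class = "facebias_error_degenerate")
  }
  dat$age_group <- factor(
    ifelse(dat$age_years < cutoff, "juvenile", "adult"),
    levels = c("adult", "juvenile")
  )
  if (any(table(factor(dat$age_group, levels = c("adult", "juvenile"))) == 0)) {
    stop_input("An age stratum is empty; the interaction model cannot be fitted",
               class = "facebias_error_degenerate")
  }
  if (length(unique(dat$age_years)) < 3) {
    stop_input("Need at least 3 distinct ages for the quadratic age model",
               class = "facebias_error_degenerate")
  }
  suite <- list(
    linear_age = fit_fb_lmm(
      score ~ sex + age_years + (1 | group_id), dat, REML = REML
    ),
    log_age = fit_fb_lmm(
      score ~ sex + log(age_years) + (1 | group_id), dat, REML = REML
    ),
    poly_age = fit_fb_lmm(
      score ~ sex + poly(age_years, 2) + (1 | group_id), dat, REML = REML
    ),
    age_by_group_interaction = fit_fb_lmm(
      score ~ sex + age_group + age_group:age_years + (1 | group_id),
      dat, REML = REML,
      scale_note = "age_group:age_years terms are the per-stratum age slopes"
    )
  )
  class(suite) <- "fb_age_suite"
  suite
}

#' Extract the juvenile and adult age slopes from the interaction model
#'
#' @param suite An `fb_age_suite` from [fit_age_models()].
#' @return Tibble with one row per age stratum's slope.
#' @export
age_slopes <- function(suite) {
  if (!inherits(suite, "fb_age_suite")) stop_input("`suite` must be an fb_age_suite")
  ct <- suite$age_by_group_interaction$coefficients
  out <- ct[grepl("^age_group.*:age_years$", ct$term), , drop = FALSE]
  out$stratum <- sub(":age_years$", "", sub("^age_group", "", out$term))
  out[c("stratum", "estimate", "std.error", "df", "statistic", "p.value")]
}
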