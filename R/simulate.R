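# Synthetic study generator: cohort, maternal-care records, latent skill,
# and trial-level looking times for the three experiments.

EXPRESSIONS_EXP1 <- c("bared_teeth", "threat", "scream")
INTENSITIES_EXP2 <- c(0.25, 0.50, 0.75, 1.00)
SEQUENCE_EXPRESSIONS <- c("threat", "scream", "neutral")
VIOLATING_EXPRESSIONS <- c("threat", "scream", "bared_teeth")

# Deterministic per-module sub-stream seeds derived from the base seed.
module_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 16807) %% 2147483629) + 1L
}

# Multiplicative skill link: effects are scaled by exp(k * skill), normalised
# to cohort mean 1 so configured effects equal cohort-average effects.
skill_multiplier <- function(skills, config) {
  m <- exp(config$skill_link_scale * skills$skill)
  m / mean(m)
}

#' Generate a synthetic cohort with maternal-care records and latent skill
#'
#' Draws subjects (sex, age, social group, mother), maternal scan/focal
#' records for the configured fraction of the cohort, and each subject's
#' latent facial-expression-processing skill
#' `skill = beta_groom*grooming + beta_cradle*cradling + beta_approach*approaches +
#' beta_restrain*restraints + age_curve(age) + group RE + mother RE + residual`.
#' Subjects without maternal records contribute no maternal or mother-RE terms.
#'
#' @param config An [sim_config()] object.
#' @return A list with tibbles `subjects` (subject_id, sex, age_years,
#'   group_id, mother_id, age_group), `maternal` (scan and focal counts plus
#'   grooming/cradling proportions), and `skills` (subject_id, skill).
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 2, n_subjects = 12, n_groups = 3))
#' cohort$subjects
#' @export
simulate_cohort <- function(config) {
  validate_config(config)
  with_seed(module_seed(config$seed, 1L), {
    n <- as.integer(config$n_subjects)
    subject_id <- sprintf("S%04d", seq_len(n))
    sex <- ifelse(runif(n) < config$prob_female, "female", "male")

    # Age mixture mirroring the juvenile-heavy cohort (45 of 83 under 5).
    lo <- config$age_range[1]
    hi <- config$age_range[2]
    cut <- 5
    if (hi <= cut) {
      age <- runif(n, lo, hi)
    } else if (lo >= cut) {
      age <- runif(n, lo, hi)
    } else {
      juv <- runif(n) < 45 / 83
      age <- ifelse(juv, runif(n, lo, cut), runif(n, cut, hi))
    }

    group_id <- sprintf("G%02d", sample(rep_len(seq_len(config$n_groups), n)))

    n_mat <- round(config$maternal_fraction * n)
    mat_idx <- sort(sample.int(n, n_mat))
    mother_id <- rep(NA_character_, n)
    if (n_mat > 0) {
      n_mothers <- max(1L, ceiling(0.85 * n_mat))
      mother_id[mat_idx] <- sprintf("M%03d", sample.int(n_mothers, n_mat, replace = TRUE))
    }

    subjects <- tibble(
      subject_id = subject_id,
      sex = factor(sex, levels = c("female", "male")),
      age_years = age,
      group_id = group_id,
      mother_id = mother_id,
      age_group = factor(
        ifelse(age < 5, "juvenile", "adult"),
        levels = c("adult", "juvenile")
      )
    )

    n_scans <- as.integer(config$n_focals * config$scans_per_focal)
    maternal <- tibble(
      subject_id = subject_id[mat_idx],
      n_scans = rep(n_scans, n_mat),
      n_groom_scans = rbetabinom(n_mat, n_scans, config$groom_mean, config$groom_phi),
      n_cradle_scans = rbetabinom(n_mat, n_scans, config$cradle_mean, config$cradle_phi),
      approach_count = rpois(n_mat, config$approach_rate),
      restrain_count = rpois(n_mat, config$restrain_rate)
    )
    maternal$grooming_score <- maternal$n_groom_scans / maternal$n_scans
    maternal$cradling_score <- maternal$n_cradle_scans / maternal$n_scans

    care <- rep(0, n)
    if (n_mat > 0) {
      care[mat_idx] <- config$beta_groom * maternal$grooming_score +
        config$beta_cradle * maternal$cradling_score +
        config$beta_approach * maternal$approach_count +
        config$beta_restrain * maternal$restrain_count
    }

    u_group <- rnorm(config$n_groups, 0, config$sd_group)
    names(u_group) <- sprintf("G%02d", seq_len(config$n_groups))
    mothers <- unique(mother_id[!is.na(mother_id)])
    u_mother_tab <- setNames(rnorm(length(mothers), 0, config$sd_mother), mothers)
    u_mother <- ifelse(is.na(mother_id), 0, u_mother_tab[mother_id])

    skill <- care + age_skill(age, config$age_curve) +
      u_group[group_id] + u_mother + rnorm(n, 0, config$sd_resid)

    list(
      subjects = subjects,
      maternal = maternal,
      skills = tibble(subject_id = subject_id, skill = unname(skill))
    )
  })
}

#' Generate paired-presentation (expression vs. neutral) trials
#'
#' Each trial shows an expression (bared-teeth, threat or scream) against a
#' neutral face for two 5-s windows with sides swapped between windows. The
#' per-trial looking proportion at the expression is drawn around
#' `0.5 + effect * exp(k * skill) / mean(exp(k * skill))`, total looking time
#' is truncated-normal positive, and a `dropout_rate` fraction of trials
#' fails inclusion because one image was never looked at.
#'
#' @param subjects,skills Tibbles from [simulate_cohort()].
#' @param config An [sim_config()] object.
#' @return Tibble with one row per trial: `trial_id`, `subject_id`,
#'   `group_id`, `expression`, `stimulus_pair_id`, `expression_side_w1`,
#'   `look_expression_s`, `look_neutral_s`, `includable`.
#' @export
simulate_exp1_trials <- function(subjects, skills, config) {
  validate_config(config)
  with_seed(module_seed(config$seed, 2L), {
    n_trials <- as.integer(config$n_trials_exp1)
    if (n_trials == 0) return(empty_exp1())
    m <- skill_multiplier(skills, config)
    effects <- c(
      bared_teeth = config$effect_bt_bias,
      threat = config$effect_threat_bias,
      scream = config$effect_scream_bias
    )

    ns <- nrow(subjects)
    idx <- rep(seq_len(ns), each = n_trials)
    nt <- length(idx)
    # Balanced expression cycle per subject, shuffled within subject.
    expr <- rep(EXPRESSIONS_EXP1[(seq_len(n_trials) - 1) %% 3 + 1], ns)
    expr <- expr[order(idx, runif(nt))]
    trials <- tibble(
      subject_id = subjects$subject_id[idx],
      group_id = subjects$group_id[idx],
      expression = expr,
      stimulus_pair_id = sample.int(3L, nt, replace = TRUE),
      mult = m[idx]
    )
    trials$trial_id <- sprintf("e1_%05d", seq_len(nt))
    trials$expression_side_w1 <- sample(c("left", "right"), nt, replace = TRUE)

    p_mean <- pmin(pmax(0.5 + effects[trials$expression] * trials$mult, 0.02), 0.98)
    p <- rtnorm(nt, p_mean, config$sd_bias, 0.01, 0.99)
    total <- rtnorm(nt, config$look_total_mean, config$look_total_sd, 0.5, 9.6)
    trials$look_expression_s <- p * total
    trials$look_neutral_s <- (1 - p) * total

    drop <- runif(nt) < config$dropout_rate
    drop_expr <- runif(nt) < 0.5
    trials$look_expression_s[drop & drop_expr] <- 0
    trials$look_neutral_s[drop & !drop_expr] <- 0
    trials$includable <- trials$look_expression_s > 0 & trials$look_neutral_s > 0

    trials$mult <- NULL
    trials[c("trial_id", "subject_id", "group_id", "expression",
             "stimulus_pair_id", "expression_side_w1",
             "look_expression_s", "look_neutral_s", "includable")]
  })
}

#' Generate threat-intensity trials
#'
#' Avatar threat faces at intensities 0.25/0.5/0.75/1 are paired with a
#' neutral face; the expected looking proportion at the threat is
#' `0.5 + slope * (intensity - intensity_center)` scaled by the subject's
#' skill multiplier. Structure otherwise parallels [simulate_exp1_trials()].
#'
#' @inheritParams simulate_exp1_trials
#' @return Tibble with `trial_id`, `subject_id`, `group_id`, `intensity`,
#'   `stimulus_pair_id`, `expression_side_w1`, `look_expression_s`,
#'   `look_neutral_s`, `includable`.
#' @export
simulate_exp2_trials <- function(subjects, skills, config) {
  validate_config(config)
  with_seed(module_seed(config$seed, 3L), {
    n_trials <- as.integer(config$n_trials_exp2)
    if (n_trials == 0) return(empty_exp2())
    m <- skill_multiplier(skills, config)

    ns <- nrow(subjects)
    idx <- rep(seq_len(ns), each = n_trials)
    nt <- length(idx)
    ints <- rep(INTENSITIES_EXP2[(seq_len(n_trials) - 1) %% 4 + 1], ns)
    ints <- ints[order(idx, runif(nt))]
    trials <- tibble(
      subject_id = subjects$subject_id[idx],
      group_id = subjects$group_id[idx],
      intensity = ints,
      mult = m[idx]
    )
    trials$trial_id <- sprintf("e2_%05d", seq_len(nt))
    trials$stimulus_pair_id <- 1L
    trials$expression_side_w1 <- sample(c("left", "right"), nt, replace = TRUE)

    p_mean <- 0.5 + config$effect_intensity_slope *
      (trials$intensity - config$intensity_center) * trials$mult
    p_mean <- pmin(pmax(p_mean, 0.02), 0.98)
    p <- rtnorm(nt, p_mean, config$sd_bias, 0.01, 0.99)
    total <- rtnorm(nt, config$look_total_mean, config$look_total_sd, 0.5, 9.6)
    trials$look_expression_s <- p * total
    trials$look_neutral_s <- (1 - p) * total

    drop <- runif(nt) < config$dropout_rate
    drop_expr <- runif(nt) < 0.5
    trials$look_expression_s[drop & drop_expr] <- 0
    trials$look_neutral_s[drop & !drop_expr] <- 0
    trials$includable <- trials$look_expression_s > 0 & trials$look_neutral_s > 0

    trials$mult <- NULL
    trials[c("trial_id", "subject_id", "group_id", "intensity",
             "stimulus_pair_id", "expression_side_w1",
             "look_expression_s", "look_neutral_s", "includable")]
  })
}

#' Generate expectation-violation sequence trials
#'
#' Five same-expression 3-s images are followed by a sixth, different
#' expression. Looking times at images 1-5 follow a subject-level declining
#' linear trend plus noise; the sixth-image time is the trend's value at
#' position 6 plus `effect_violation_excess` scaled by the subject's skill
#' multiplier, plus noise. A fraction of includable trials has exactly one
#' of images 1-5 missing; dropout trials miss the final image or two initial
#' images and fail inclusion.
#'
#' @inheritParams simulate_exp1_trials
#' @return Tibble with `trial_id`, `subject_id`, `group_id`,
#'   `sequence_expression`, `violating_expression`, `look_1` ... `look_6`
#'   (NA = image not looked at), `includable`.
#' @export
simulate_exp3_trials <- function(subjects, skills, config) {
  validate_config(config)
  with_seed(module_seed(config$seed, 4L), {
    n_trials <- as.integer(config$n_trials_exp3)
    if (n_trials == 0) return(empty_exp3())
    m <- skill_multiplier(skills, config)
    ns <- nrow(subjects)

    idx <- rep(seq_len(ns), each = n_trials)
    nt <- length(idx)
    seq_expr <- sample(SEQUENCE_EXPRESSIONS, nt, replace = TRUE)
    viol_expr <- vapply(
      seq_expr,
      function(s) sample(setdiff(VIOLATING_EXPRESSIONS, s), 1L),
      character(1)
    )

    # Subject-level habituation trend.
    a <- rnorm(ns, config$exp3_look_start, 0.3)
    b <- rnorm(ns, config$exp3_habituation, 0.04)

    looks <- matrix(NA_real_, nt, 6)
    for (j in 1:5) {
      mu <- pmin(pmax(a[idx] + b[idx] * j, 0.3), 2.8)
      looks[, j] <- rtnorm(nt, mu, config$sd_look, 0, 3)
    }
    mu6 <- pmin(pmax(a[idx] + b[idx] * 6 + config$effect_violation_excess * m[idx], 0.3), 2.9)
    looks[, 6] <- rtnorm(nt, mu6, config$sd_look, 0, 3)

    # One-missing-initial-image fraction (still includable).
    miss_one <- runif(nt) < config$exp3_missing_rate
    which_miss <- sample.int(5L, nt, replace = TRUE)
    looks[cbind(which(miss_one), which_miss[miss_one])] <- NA_real_

    # Dropout: lose the final image, or two initial images.
    drop <- runif(nt) < config$dropout_rate
    drop_final <- runif(nt) < 0.5
    for (i in which(drop)) {
      if (drop_final[i]) {
        looks[i, 6] <- NA_real_
      } else {
        gone <- sample(setdiff(1:5, if (miss_one[i]) which_miss[i] else integer()), 2L)
        looks[i, gone] <- NA_real_
      }
    }

    trials <- tibble(
      trial_id = sprintf("e3_%05d", seq_len(nt)),
      subject_id = subjects$subject_id[idx],
      group_id = subjects$group_id[idx],
      sequence_expression = seq_expr,
      violating_expression = unname(viol_expr)
    )
    colnames(looks) <- paste0("look_", 1:6)
    trials <- dplyr::bind_cols(trials, as_tibble(looks))
    trials$includable <- rowSums(!is.na(looks[, 1:5, drop = FALSE])) >= 4 &
      !is.na(looks[, 6])
    trials
  })
}

empty_exp1 <- function() {
  tibble(
    trial_id = character(), subject_id = character(), group_id = character(),
    expression = character(), stimulus_pair_id = integer(),
    expression_side_w1 = character(), look_expression_s = numeric(),
    look_neutral_s = numeric(), includable = logical()
  )
}

empty_exp2 <- function() {
  tibble(
    trial_id = character(), subject_id = character(), group_id = character(),
    intensity = numeric(), stimulus_pair_id = integer(),
    expression_side_w1 = character(), look_expression_s = numeric(),
    look_neutral_s = numeric(), includable = logical()
  )
}

empty_exp3 <- function() {
  out <- tibble(
    trial_id = character(), subject_id = character(), group_id = character(),
    sequence_expression = character(), violating_expression = character()
  )
  for (j in 1:6) out[[paste0("look_", j)]] <- numeric()
  out$includable <- logical()
  out
}

#' Simulate a complete synthetic study
#'
#' Composes [simulate_cohort()] and the three trial generators under one
#' seed. Identical configurations produce identical studies.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `fb_study`: `config`, `subjects`, `maternal`,
#'   `skills`, `exp1`, `exp2`, `exp3`.
#' @examples
#' study <- simulate_study(sim_config(seed = 7, n_subjects = 15, n_groups = 3))
#' names(study)
#' @export
simulate_study <- function(config) {
  validate_config(config)
  cohort <- simulate_cohort(config)
  out <- list(
    config = config,
    subjects = cohort$subjects,
    maternal = cohort$maternal,
    skills = cohort$skills,
    exp1 = simulate_exp1_trials(cohort$subjects, cohort$skills, config),
    exp2 = simulate_exp2_trials(cohort$subjects, cohort$skills, config),
    exp3 = simulate_exp3_trials(cohort$subjects, cohort$skills, config)
  )
  class(out) <- "fb_study"
  out
}

#' @export
print.fb_study <- function(x, ...) {
  cat("<fb_study>", nrow(x$subjects), "subjects in",
      length(unique(x$subjects$group_id)), "groups;",
      nrow(x$maternal), "maternal records\n")
  cat("  trials: exp1 =", nrow(x$exp1), " exp2 =", nrow(x$exp2),
      " exp3 =", nrow(x$exp3), "\n")
  invisible(x)
}
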