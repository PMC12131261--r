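#' Simulation configuration for synthetic looking-time studies
#'
#' Builds the configuration object consumed by [simulate_study()] and the
#' per-stage generators. Defaults emulate the study conditions of the
#' macaque facial-expression battery this package analyses: 83 subjects in
#' 15 social groups (about two thirds female), ages 1-16 years, maternal
#' observation records for roughly half the cohort, three paired-presentation
#' trials (one per expression) and four intensity trials (one per intensity
#' level) per subject, one expectation-violation sequence per subject, and
#' effect sizes at the values the population-level analyses report
#' (scream bias -0.07, bared-teeth +0.05, threat +0.01 on the proportion
#' scale; intensity slope 0.12 per unit intensity; 0.27 s violation excess).
#'
#' @param seed Integer seed; fixing it makes every generated dataset
#'   byte-identical across calls.
#' @param n_subjects,n_groups Cohort size and number of social groups
#'   (`n_groups <= n_subjects`).
#' @param prob_female Probability a subject is female.
#' @param age_range Length-2 numeric, minimum and maximum age in years
#'   (subjects are at least 1 year old).
#' @param maternal_fraction Fraction of subjects with maternal-care records
#'   (and a known mother).
#' @param n_trials_exp1 Paired-presentation trials per subject; expressions
#'   (bared-teeth, threat, scream) are cycled so counts stay balanced.
#' @param n_trials_exp2 Intensity trials per subject; the four intensities
#'   (0.25, 0.5, 0.75, 1) are cycled.
#' @param n_trials_exp3 Expectation-violation sequences per subject.
#' @param effect_scream_bias,effect_bt_bias,effect_threat_bias Signed mean
#'   deviation of the looking proportion from 0.5 on scream, bared-teeth and
#'   threat trials for a subject of average skill.
#' @param effect_intensity_slope Change in expected looking proportion per
#'   unit threat intensity (intensity on the 0.25-1 scale).
#' @param intensity_center Intensity at which the expected proportion is
#'   exactly 0.5. Default 0: a zero-intensity threat is a neutral face, so
#'   indifference at zero intensity is the principled anchor.
#' @param effect_violation_excess Seconds added to the sixth-image looking
#'   time beyond the habituation trend, for a subject of average skill.
#' @param skill_link_scale Scale `k` of the multiplicative skill link: each
#'   subject's effect sizes are multiplied by `exp(k * skill)`, normalised to
#'   cohort mean 1 so configured effects equal cohort-average effects.
#' @param beta_groom,beta_cradle Effects of the maternal grooming and
#'   cradling scan proportions on latent skill.
#' @param beta_approach,beta_restrain Effects of maternal approach and
#'   restraint counts (per nine-focal observation battery) on latent skill.
#' @param age_curve List with `juvenile_slope` (skill gain per year before
#'   the plateau) and `plateau_age` (years; default 5, the juvenile/adult
#'   cutoff). Skill rises linearly to the plateau and is flat afterwards.
#' @param sd_group,sd_mother,sd_resid Standard deviations of the group and
#'   mother random intercepts and of the subject-level residual in the latent
#'   skill model.
#' @param sd_bias Trial-level standard deviation of the looking proportion.
#' @param look_total_mean,look_total_sd Mean/SD of total looking seconds per
#'   paired trial (both 5-s windows combined; truncated to (0.5, 9.6)).
#' @param exp3_look_start Expected looking seconds at the first sequence
#'   image.
#' @param exp3_habituation Expected change in looking seconds per image
#'   position (negative: habituation).
#' @param sd_look Per-image looking-time noise SD (seconds).
#' @param exp3_missing_rate Fraction of includable sequences in which exactly
#'   one of images 1-5 was not looked at.
#' @param dropout_rate Probability a trial fails the inclusion criteria
#'   (paired trials: one image never looked at; sequences: too few initial
#'   looks or no final look).
#' @param n_focals,scans_per_focal Maternal observation battery: number of
#'   10-min focals and 30-s scans per focal (9 x 20 = 180 scans).
#' @param groom_mean,groom_phi,cradle_mean,cradle_phi Beta-binomial mean and
#'   precision for grooming/cradling scan counts.
#' @param approach_rate,restrain_rate Poisson means for maternal approach and
#'   restraint counts over the battery.
#'
#' @return A list of class `fb_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_subjects = 20, n_groups = 4)
#' study <- simulate_study(cfg)
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 83L,
                       n_groups = 15L,
                       prob_female = 56 / 83,
                       age_range = c(1, 16),
                       maternal_fraction = 40 / 83,
                       n_trials_exp1 = 3L,
                       n_trials_exp2 = 4L,
                       n_trials_exp3 = 1L,
                       effect_scream_bias = -0.07,
                       effect_bt_bias = 0.05,
                       effect_threat_bias = 0.01,
                       effect_intensity_slope = 0.12,
                       intensity_center = 0,
                       effect_violation_excess = 0.27,
                       skill_link_scale = 0.25,
                       beta_groom = 0.4,
                       beta_cradle = 0.3,
                       beta_approach = 0.03,
                       beta_restrain = -0.03,
                       age_curve = list(juvenile_slope = 0.17, plateau_age = 5),
                       sd_group = 0.3,
                       sd_mother = 0.3,
                       sd_resid = 0.9,
                       sd_bias = 0.12,
                       look_total_mean = 6,
                       look_total_sd = 1.5,
                       exp3_look_start = 2.2,
                       exp3_habituation = -0.15,
                       sd_look = 0.3,
                       exp3_missing_rate = 0.1,
                       dropout_rate = 0.25,
                       n_focals = 9L,
                       scans_per_focal = 20L,
                       groom_mean = 0.10,
                       groom_phi = 12,
                       cradle_mean = 0.35,
                       cradle_phi = 10,
                       approach_rate = 4,
                       restrain_rate = 1.5) {
  cfg <- as.list(environment())
  class(cfg) <- "fb_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk_num <- function(field, lo = -Inf, hi = Inf, len = 1L) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != len || anyNA(x) || any(x < lo) || any(x > hi)) {
      stop_config(
        sprintf("Invalid configuration field '%s'", field),
        field = field
      )
    }
  }
  chk_num("seed")
  chk_num("n_subjects", lo = 1)
  chk_num("n_groups", lo = 1)
  if (cfg$n_groups > cfg$n_subjects) {
    stop_config("'n_groups' must not exceed 'n_subjects'", field = "n_groups")
  }
  for (f in c("prob_female", "maternal_fraction", "dropout_rate",
              "exp3_missing_rate", "groom_mean", "cradle_mean")) {
    chk_num(f, lo = 0, hi = 1)
  }
  chk_num("age_range", len = 2L)
  if (cfg$age_range[1] < 1 || diff(cfg$age_range) < 0) {
    stop_config("'age_range' must satisfy 1 <= min <= max", field = "age_range")
  }
  for (f in c("n_trials_exp1", "n_trials_exp2", "n_trials_exp3")) chk_num(f, lo = 0)
  for (f in c("sd_group", "sd_mother", "sd_resid", "sd_bias", "sd_look",
              "look_total_sd", "groom_phi", "cradle_phi",
              "approach_rate", "restrain_rate")) {
    chk_num(f, lo = 0)
  }
  for (f in c("effect_scream_bias", "effect_bt_bias", "effect_threat_bias",
              "effect_intensity_slope", "intensity_center",
              "effect_violation_excess", "skill_link_scale",
              "beta_groom", "beta_cradle", "beta_approach", "beta_restrain",
              "look_total_mean", "exp3_look_start", "exp3_habituation")) {
    chk_num(f)
  }
  chk_num("n_focals", lo = 1)
  chk_num("scans_per_focal", lo = 1)
  if (!is.list(cfg$age_curve) ||
      !all(c("juvenile_slope", "plateau_age") %in% names(cfg$age_curve))) {
    stop_config(
      "'age_curve' must be a list with 'juvenile_slope' and 'plateau_age'",
      field = "age_curve"
    )
  }
  invisible(cfg)
}

# Latent-skill contribution of age: linear rise up to the plateau, flat after.
age_skill <- function(age, age_curve) {
  age_curve$juvenile_slope * (pmin(age, age_curve$plateau_age) - age_curve$plateau_age)
}
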