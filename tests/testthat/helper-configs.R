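# Shared configurations and small fixtures built in code.

small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_subjects = 20, n_groups = 4, ...)
}

# All generator effects zero: the null data-generating process.
null_config <- function(seed = 1, n_subjects = 40, n_groups = 8, ...) {
  sim_config(
    seed = seed, n_subjects = n_subjects, n_groups = n_groups,
    effect_scream_bias = 0, effect_bt_bias = 0, effect_threat_bias = 0,
    effect_intensity_slope = 0, effect_violation_excess = 0,
    beta_groom = 0, beta_cradle = 0, beta_approach = 0, beta_restrain = 0,
    age_curve = list(juvenile_slope = 0, plateau_age = 5),
    ...
  )
}

# Zero random-effect variance: mixed models should collapse to OLS.
no_re_config <- function(seed = 1, n_subjects = 60, n_groups = 6, ...) {
  sim_config(
    seed = seed, n_subjects = n_subjects, n_groups = n_groups,
    sd_group = 0, sd_mother = 0, dropout_rate = 0,
    ...
  )
}

quiet_pipeline <- function(expr) {
  suppressWarnings(suppressMessages(expr))
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# Two-coder duration ratings on 9 videos; ICC oracle values frozen from an
# independent reference implementation of the McGraw & Wong forms.
icc_fixture <- function() {
  tibble::tibble(
    unit = rep(1:9, 2),
    coder = rep(c("a", "b"), each = 9),
    value = c(
      4.2, 2.1, 6.3, 3.3, 5.0, 1.2, 7.4, 2.8, 4.9,
      4.0, 2.4, 6.1, 3.6, 4.7, 1.5, 7.0, 3.1, 5.2
    )
  )
}

icc_noisy_fixture <- function() {
  tibble::tibble(
    unit = rep(1:9, 2),
    coder = rep(c("a", "b"), each = 9),
    value = c(
      4.2, 2.1, 6.3, 3.3, 5.0, 1.2, 7.4, 2.8, 4.9,
      4.2123015336, 5.0874553751, 3.5586214464, -5.6059183876, 0.4532921483,
      -8.71646555, 8.001436026, 16.2021524555, -0.0220651855
    )
  )
}

# Hand-built two-trial paired manifest/events for side-swap bookkeeping.
paired_manifest <- function() {
  tibble::tibble(
    trial_id = c("t1", "t2"),
    subject_id = c("S1", "S2"),
    group_id = c("G1", "G1"),
    experiment = "exp1",
    expression = c("scream", "threat"),
    intensity = NA_real_,
    sequence_expression = NA_character_,
    violating_expression = NA_character_,
    stimulus_pair_id = 1L,
    expression_side_w1 = c("left", "right"),
    n_windows = 2L,
    w1_start = 0, w1_stop = 5,
    w2_start = 5.5, w2_stop = 10.5,
    w3_start = NA_real_, w3_stop = NA_real_,
    w4_start = NA_real_, w4_stop = NA_real_,
    w5_start = NA_real_, w5_stop = NA_real_,
    w6_start = NA_real_, w6_stop = NA_real_
  )
}
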