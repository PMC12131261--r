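test_that("cohort matches configured sizes and subject invariants", {
  cfg <- sim_config(seed = 5)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort$subjects), 83)
  expect_equal(length(unique(cohort$subjects$group_id)), 15)
  expect_true(all(cohort$subjects$age_years >= 1))
  expect_equal(
    as.character(cohort$subjects$age_group),
    ifelse(cohort$subjects$age_years < 5, "juvenile", "adult")
  )
  expect_equal(nrow(cohort$maternal), round(cfg$maternal_fraction * 83))
  with(cohort$maternal, {
    expect_true(all(n_groom_scans >= 0 & n_groom_scans <= n_scans))
    expect_true(all(n_cradle_scans >= 0 & n_cradle_scans <= n_scans))
    expect_equal(grooming_score, n_groom_scans / n_scans)
    expect_equal(cradling_score, n_cradle_scans / n_scans)
  })
  # subjects with maternal data have a mother, others do not
  has_mat <- cohort$subjects$subject_id %in% cohort$maternal$subject_id
  expect_true(all(!is.na(cohort$subjects$mother_id[has_mat])))
  expect_true(all(is.na(cohort$subjects$mother_id[!has_mat])))
})

test_that("identical configurations give identical studies", {
  cfg <- small_config(seed = 42)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  for (part in c("subjects", "maternal", "skills", "exp1", "exp2", "exp3")) {
    expect_identical(s1[[part]], s2[[part]])
  }
  s3 <- simulate_study(small_config(seed = 43))
  expect_false(identical(s1$exp1$look_expression_s, s3$exp1$look_expression_s))
})

test_that("under the null generative model skill is unrelated to maternal care", {
  cfg <- null_config(
    seed = 9, n_subjects = 10000, n_groups = 20,
    sd_group = 0, sd_mother = 0, maternal_fraction = 1
  )
  cohort <- simulate_cohort(cfg)
  dat <- dplyr::inner_join(cohort$maternal, cohort$skills, by = "subject_id")
  expect_lt(abs(cor(dat$grooming_score, dat$skill)), 0.03)
  # zero effects, zero RE variance: skill ~ N(0, sd_resid^2)
  expect_lt(abs(mean(cohort$skills$skill)), 0.03)
  expect_lt(abs(sd(cohort$skills$skill) - cfg$sd_resid), 0.03)
})

test_that("paired-trial looking proportions track the configured effects", {
  cfg <- sim_config(seed = 13, n_subjects = 2000, n_groups = 15, dropout_rate = 0)
  cohort <- simulate_cohort(cfg)
  tr <- simulate_exp1_trials(cohort$subjects, cohort$skills, cfg)
  bias <- tr$look_expression_s / (tr$look_expression_s + tr$look_neutral_s)
  by_expr <- tapply(bias, tr$expression, mean)
  expect_lt(abs(unname(by_expr["scream"]) - 0.43), 0.012)
  expect_lt(abs(unname(by_expr["bared_teeth"]) - 0.55), 0.012)
  # null case
  cfg0 <- null_config(seed = 13, n_subjects = 2000, n_groups = 15, dropout_rate = 0)
  cohort0 <- simulate_cohort(cfg0)
  tr0 <- simulate_exp1_trials(cohort0$subjects, cohort0$skills, cfg0)
  bias0 <- tr0$look_expression_s / (tr0$look_expression_s + tr0$look_neutral_s)
  expect_lt(abs(mean(bias0) - 0.5), 0.007)
})

test_that("dropout flags the configured fraction of trials", {
  cfg <- sim_config(seed = 21, n_subjects = 1500, n_groups = 10, dropout_rate = 0.3)
  st <- simulate_study(cfg)
  frac <- 1 - mean(c(st$exp1$includable, st$exp2$includable, st$exp3$includable))
  expect_lt(abs(frac - 0.3), 0.02)
  cfg1 <- small_config(seed = 3, dropout_rate = 1)
  st1 <- simulate_study(cfg1)
  expect_false(any(st1$exp1$includable))
  expect_false(any(st1$exp2$includable))
  expect_false(any(st1$exp3$includable))
})

test_that("intensity trials use only the four intensity levels, balanced", {
  cfg <- small_config(seed = 8)
  cohort <- simulate_cohort(cfg)
  tr <- simulate_exp2_trials(cohort$subjects, cohort$skills, cfg)
  expect_true(all(tr$intensity %in% c(0.25, 0.5, 0.75, 1)))
  expect_true(all(table(tr$intensity) == 20))
})

test_that("sequence trials respect expression constraints and missingness", {
  cfg <- sim_config(
    seed = 15, n_subjects = 1000, n_groups = 10,
    n_trials_exp3 = 2L, exp3_missing_rate = 0.3, dropout_rate = 0
  )
  cohort <- simulate_cohort(cfg)
  tr <- simulate_exp3_trials(cohort$subjects, cohort$skills, cfg)
  expect_true(all(tr$sequence_expression %in% c("threat", "scream", "neutral")))
  expect_true(all(tr$violating_expression %in% c("threat", "scream", "bared_teeth")))
  expect_true(all(tr$violating_expression != tr$sequence_expression))
  n_initial <- rowSums(!is.na(as.matrix(tr[paste0("look_", 1:5)])))
  expect_lt(abs(mean(n_initial == 4) - 0.3), 0.04)
})

test_that("with zero excess and zero image noise the trend extrapolates exactly", {
  cfg <- sim_config(
    seed = 30, n_subjects = 400, n_groups = 8,
    effect_violation_excess = 0, sd_look = 0, dropout_rate = 0,
    exp3_missing_rate = 0
  )
  cohort <- simulate_cohort(cfg)
  tr <- simulate_exp3_trials(cohort$subjects, cohort$skills, cfg)
  rec <- violation_records(tr)
  # exact except for the few trials whose trend mean hit the 0-3 s clamp
  expect_lt(stats::median(abs(rec$excess_s)), 1e-10)
  expect_gt(mean(abs(rec$excess_s) < 1e-10), 0.9)
})

test_that("sixth-image excess recovers the configured violation effect", {
  cfg <- sim_config(seed = 31, n_subjects = 3000, n_groups = 15, dropout_rate = 0)
  cohort <- simulate_cohort(cfg)
  tr <- simulate_exp3_trials(cohort$subjects, cohort$skills, cfg)
  rec <- violation_records(tr)
  expect_lt(abs(mean(rec$excess_s) - 0.27), 0.025)
})
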