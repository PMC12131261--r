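test_that("the orthogonal polynomial basis is orthonormal and spans the raw fit", {
  b <- ortho_poly(c(1, 2, 3), 2)
  expect_equal(b[, 1], c(-1, 0, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(b[, 2], c(1, -2, 1) / sqrt(6), tolerance = 1e-12)
  set.seed(7)
  x <- runif(40, 1, 16)
  bb <- ortho_poly(x, 2)
  expect_equal(crossprod(bb), diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colSums(bb), c(0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  y <- 0.3 + 0.2 * x - 0.05 * x^2 + rnorm(40, 0, 0.1)
  f1 <- lm(y ~ bb)
  f2 <- lm(y ~ x + I(x^2))
  expect_equal(unname(fitted(f1)), unname(fitted(f2)), tolerance = 1e-10)
  expect_error(ortho_poly(c(1, 1, 2), 2), class = "facebias_error_degenerate")
})

test_that("maternal model recovers OLS when random variances are zero", {
  st <- simulate_study(no_re_config(seed = 62, n_subjects = 200,
                                    maternal_fraction = 1))
  comp <- quiet_pipeline(study_composite(st))
  fit <- quiet_pipeline(fit_maternal_model(comp, st$subjects, st$maternal))
  # the OLS identity presumes the variance estimates sit at the boundary
  vc <- tidy(fit, effects = "ran_pars")
  expect_true(all(vc$variance[vc$group != "Residual"] < 1e-8))
  dat <- comp |>
    dplyr::inner_join(st$subjects, by = "subject_id") |>
    dplyr::inner_join(st$maternal, by = "subject_id")
  ols <- lm(score ~ grooming_score + cradling_score + approach_count +
              restrain_count + sex + poly(age_years, 2), data = dat)
  expect_true(fit$singular) # zero-variance REs are reported, not dropped
  expect_equal(unname(tidy(fit)$estimate), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(tidy(fit)$term[1:6],
               c("(Intercept)", "grooming_score", "cradling_score",
                 "approach_count", "restrain_count", "sexmale"))
})

test_that("stronger maternal grooming strictly increases the fitted coefficient", {
  est <- vapply(c(0, 1.5, 3), function(b) {
    cfg <- sim_config(seed = 63, n_subjects = 3000, n_groups = 20,
                      maternal_fraction = 1, beta_groom = b)
    st <- simulate_study(cfg)
    comp <- quiet_pipeline(study_composite(st))
    fit <- quiet_pipeline(fit_maternal_model(comp, st$subjects, st$maternal))
    ct <- tidy(fit)
    ct$estimate[ct$term == "grooming_score"]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("a rising-then-flat age curve yields a juvenile slope and adult plateau", {
  cfg <- sim_config(seed = 65, n_subjects = 2000, n_groups = 15,
                    age_curve = list(juvenile_slope = 0.8, plateau_age = 5))
  st <- simulate_study(cfg)
  comp <- quiet_pipeline(study_composite(st))
  suite <- quiet_pipeline(fit_age_models(comp, st$subjects))
  expect_named(
    suite,
    c("linear_age", "log_age", "poly_age", "age_by_group_interaction")
  )
  sl <- age_slopes(suite)
  juv <- sl[sl$stratum == "juvenile", ]
  adu <- sl[sl$stratum == "adult", ]
  expect_gt(juv$estimate, 0)
  expect_lt(juv$p.value, 0.05)
  expect_lt(abs(adu$estimate), 2 * adu$std.error)
  # juvenile slope agrees with a juveniles-only regression
  dat <- dplyr::inner_join(comp, st$subjects, by = "subject_id")
  juv_only <- lm(score ~ sex + age_years, data = dat[dat$age_years < 5, ])
  expect_lt(
    abs(juv$estimate - coef(juv_only)[["age_years"]]),
    2 * juv$std.error
  )
})

test_that("a flat age curve leaves all four age models null", {
  cfg <- null_config(seed = 67, n_subjects = 1500, n_groups = 15)
  st <- simulate_study(cfg)
  comp <- quiet_pipeline(study_composite(st))
  suite <- quiet_pipeline(fit_age_models(comp, st$subjects))
  ct <- tidy(suite)
  age_terms <- ct[grepl("age", ct$term), ]
  expect_true(all(abs(age_terms$estimate) < 2 * age_terms$std.error))
})

test_that("age-model guards reject degenerate inputs", {
  st <- simulate_study(small_config(seed = 69))
  comp <- quiet_pipeline(study_composite(st))
  const_age <- dplyr::mutate(st$subjects, age_years = 3)
  expect_error(quiet_pipeline(fit_age_models(comp, const_age)),
               class = "facebias_error_degenerate")
  all_juv <- dplyr::mutate(st$subjects, age_years = runif(dplyr::n(), 1, 4))
  expect_error(quiet_pipeline(fit_age_models(comp, all_juv)),
               class = "facebias_error_degenerate")
})

test_that("model estimates are invariant to subject-row permutation", {
  st <- simulate_study(small_config(seed = 71, maternal_fraction = 1))
  comp <- quiet_pipeline(study_composite(st))
  f1 <- quiet_pipeline(fit_maternal_model(comp, st$subjects, st$maternal))
  set.seed(2)
  f2 <- quiet_pipeline(fit_maternal_model(
    comp[sample.int(nrow(comp)), ],
    st$subjects[sample.int(nrow(st$subjects)), ],
    st$maternal
  ))
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-6)
})

test_that("analyze_study returns every pipeline component", {
  st <- simulate_study(sim_config(seed = 73, n_subjects = 50, n_groups = 8,
                                  maternal_fraction = 0.6))
  res <- quiet_pipeline(analyze_study(st))
  expect_named(res$exp1, c("records", "tests", "model", "contrasts"))
  expect_equal(nrow(res$exp1$tests), 3)
  expect_s3_class(res$exp2$model, "fb_lmm")
  expect_equal(nrow(res$exp1$contrasts), 3)
  expect_s3_class(res$maternal_model, "fb_lmm")
  expect_s3_class(res$age_models, "fb_age_suite")
  expect_true(all(res$composite$n_trials >= 3))
})
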