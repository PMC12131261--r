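test_that("side-swap bookkeeping attributes durations to the right image", {
  mf <- paired_manifest()
  # t1: expression left in window 1 (2.0 s looked left), right in window 2
  # (1.2 s looked right) -> look_expression_s = 3.2
  ev <- tibble::tibble(
    trial_id = c("t1", "t1", "t1"),
    coder_id = "C1",
    target = c("left_screen", "right_screen", "right_screen"),
    start_s = c(0.5, 3.0, 6.0),
    stop_s = c(2.5, 4.0, 7.2)
  )
  asm <- assemble_trials(ev, mf)
  t1 <- asm$exp1[asm$exp1$trial_id == "t1", ]
  expect_equal(t1$look_expression_s, 3.2)
  expect_equal(t1$look_neutral_s, 1.0)
  expect_true(t1$includable)
  # t2 has no events: both durations 0, not includable
  t2 <- asm$exp1[asm$exp1$trial_id == "t2", ]
  expect_equal(t2$look_expression_s, 0)
  expect_equal(t2$look_neutral_s, 0)
  expect_false(t2$includable)
})

test_that("events straddling the inter-window gap are truncated at the edges", {
  mf <- paired_manifest()[1, ]
  ev <- tibble::tibble(
    trial_id = "t1", coder_id = "C1", target = "left_screen",
    start_s = 4.0, stop_s = 6.5 # 1 s inside w1, 0.5 s of gap, 1 s inside w2
  )
  asm <- assemble_trials(ev, mf)
  t1 <- asm$exp1[1, ]
  # left is the expression in w1 and the neutral side in w2
  expect_equal(t1$look_expression_s, 1.0)
  expect_equal(t1$look_neutral_s, 1.0)
})

test_that("assembly is invariant to event-row order", {
  st <- simulate_study(small_config(seed = 11))
  dir <- withr_local_tempdir()
  write_study(st, dir)
  ev <- read_looking_events(file.path(dir, "events.csv"))
  mf <- read_trial_manifest(file.path(dir, "manifest.csv"))
  a1 <- assemble_trials(ev, mf)
  set.seed(1)
  a2 <- assemble_trials(ev[sample.int(nrow(ev)), ], mf)
  for (exp in c("exp1", "exp2", "exp3")) {
    expect_equal(
      as.data.frame(dplyr::arrange(a1[[exp]], trial_id)),
      as.data.frame(dplyr::arrange(a2[[exp]], trial_id))
    )
  }
})

test_that("per-trial looking never exceeds the stimulus-on time", {
  st <- simulate_study(small_config(seed = 19))
  dir <- withr_local_tempdir()
  write_study(st, dir)
  asm <- assemble_trials(
    read_looking_events(file.path(dir, "events.csv")),
    read_trial_manifest(file.path(dir, "manifest.csv"))
  )
  expect_true(all(asm$exp1$look_expression_s + asm$exp1$look_neutral_s <= 10 + 1e-9))
  expect_true(all(asm$exp2$look_expression_s + asm$exp2$look_neutral_s <= 10 + 1e-9))
  looks3 <- as.matrix(asm$exp3[paste0("look_", 1:6)])
  expect_true(all(rowSums(looks3, na.rm = TRUE) <= 18 + 1e-9))
  expect_true(all(looks3 <= 3 + 1e-9, na.rm = TRUE))
})

test_that("events with unknown trials error; events outside windows are dropped", {
  mf <- paired_manifest()
  bad <- tibble::tibble(
    trial_id = "nope", coder_id = "C1", target = "left_screen",
    start_s = 0, stop_s = 1
  )
  expect_error(assemble_trials(bad, mf), class = "facebias_error_validation")
  outside <- tibble::tibble(
    trial_id = c("t1", "t1"), coder_id = "C1",
    target = c("left_screen", "left_screen"),
    start_s = c(0.5, 11), stop_s = c(1.5, 12)
  )
  expect_message(asm <- assemble_trials(outside, mf), "outside")
  expect_equal(asm$exp1$look_expression_s[asm$exp1$trial_id == "t1"], 1.0)
})

test_that("a sequence trial looked at for images 1,2,3,5,6 is includable", {
  trials <- tibble::tibble(
    trial_id = "s1", subject_id = "S1", group_id = "G1",
    sequence_expression = "threat", violating_expression = "scream",
    look_1 = 1.5, look_2 = 1.4, look_3 = 1.2, look_4 = NA_real_,
    look_5 = 1.0, look_6 = 1.6, includable = NA
  )
  parts <- apply_inclusion(trials)
  expect_equal(nrow(parts$included), 1)
  expect_equal(parts$n_excluded, 0)
})

test_that("inclusion filters partition with machine-readable reasons", {
  paired <- tibble::tibble(
    look_expression_s = c(2, 0, 3), look_neutral_s = c(1, 2, 0),
    includable = NA
  )
  parts <- apply_inclusion(paired)
  expect_equal(parts$n_excluded, 2)
  expect_true(all(parts$excluded$reason == "did_not_look_both"))

  seq3 <- tibble::tibble(
    look_1 = c(1, 1, 1), look_2 = c(1, 1, 1), look_3 = c(1, 1, NA),
    look_4 = c(NA, 1, NA), look_5 = c(NA, NA, 1), look_6 = c(1, NA, 1),
    includable = NA
  )
  parts3 <- apply_inclusion(seq3)
  expect_equal(nrow(parts3$included), 0)
  expect_setequal(parts3$excluded$reason[c(1, 3)], "fewer_than_4_initial_looks")
  expect_equal(parts3$excluded$reason[2], "no_final_look")

  all_ok <- tibble::tibble(
    look_expression_s = c(2, 3), look_neutral_s = c(1, 1), includable = NA
  )
  expect_equal(apply_inclusion(all_ok)$n_excluded, 0)
})

test_that("exclusion fraction on synthetic data matches the dropout rate", {
  st <- simulate_study(sim_config(seed = 29, n_subjects = 800, n_groups = 10,
                                  dropout_rate = 0.2))
  n_all <- nrow(st$exp1) + nrow(st$exp2) + nrow(st$exp3)
  n_exc <- apply_inclusion(st$exp1)$n_excluded +
    apply_inclusion(st$exp2)$n_excluded +
    apply_inclusion(st$exp3)$n_excluded
  expect_lt(abs(n_exc / n_all - 0.2), 0.016)
})
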