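# Reading and writing study files: subject/maternal/trial tables and the
# coded looking-event dialect (interval events plus a trial manifest).

EVENT_TARGETS <- c("left_screen", "right_screen", "screen", "away")

# Presentation timing carried in the manifest, not hard-coded downstream:
# paired trials use two 5-s windows separated by a 0.5-s black screen;
# sequences use six 3-s images with 0.5-s gaps.
exp12_windows <- function() list(start = c(0, 5.5), stop = c(5, 10.5))
exp3_windows <- function() list(start = (0:5) * 3.5, stop = (0:5) * 3.5 + 3)

build_manifest <- function(study) {
  w12 <- exp12_windows()
  w3 <- exp3_windows()
  blank6 <- function(n) matrix(NA_real_, n, 6)

  mk <- function(trials, experiment) {
    n <- nrow(trials)
    out <- tibble(
      trial_id = trials$trial_id,
      subject_id = trials$subject_id,
      group_id = trials$group_id,
      experiment = experiment,
      expression = if ("expression" %in% names(trials)) trials$expression else NA_character_,
      intensity = if ("intensity" %in% names(trials)) trials$intensity else NA_real_,
      sequence_expression = if ("sequence_expression" %in% names(trials)) {
        trials$sequence_expression
      } else {
        NA_character_
      },
      violating_expression = if ("violating_expression" %in% names(trials)) {
        trials$violating_expression
      } else {
        NA_character_
      },
      stimulus_pair_id = if ("stimulus_pair_id" %in% names(trials)) {
        as.integer(trials$stimulus_pair_id)
      } else {
        NA_integer_
      },
      expression_side_w1 = if ("expression_side_w1" %in% names(trials)) {
        trials$expression_side_w1
      } else {
        NA_character_
      }
    )
    ws <- blank6(n)
    we <- blank6(n)
    if (experiment == "exp3") {
      out$n_windows <- 6L
      for (j in 1:6) {
        ws[, j] <- w3$start[j]
        we[, j] <- w3$stop[j]
      }
    } else {
      out$n_windows <- 2L
      for (j in 1:2) {
        ws[, j] <- w12$start[j]
        we[, j] <- w12$stop[j]
      }
    }
    for (j in 1:6) {
      out[[paste0("w", j, "_start")]] <- ws[, j]
      out[[paste0("w", j, "_stop")]] <- we[, j]
    }
    out
  }

  dplyr::bind_rows(
    mk(study$exp1, "exp1"),
    mk(study$exp2, "exp2"),
    mk(study$exp3, "exp3")
  )
}

build_events <- function(study, coder_id = "C1") {
  w12 <- exp12_windows()
  w3 <- exp3_windows()

  paired_events <- function(trials) {
    if (nrow(trials) == 0) return(NULL)
    rows <- vector("list", nrow(trials) * 4L)
    k <- 0L
    for (i in seq_len(nrow(trials))) {
      e_half <- trials$look_expression_s[i] / 2
      n_half <- trials$look_neutral_s[i] / 2
      for (w in 1:2) {
        e_side <- if (w == 1) trials$expression_side_w1[i] else {
          if (trials$expression_side_w1[i] == "left") "right" else "left"
        }
        n_side <- if (e_side == "left") "right" else "left"
        t0 <- w12$start[w] + 0.1
        if (e_half > 0) {
          k <- k + 1L
          rows[[k]] <- list(
            trial_id = trials$trial_id[i], coder_id = coder_id,
            target = paste0(e_side, "_screen"),
            start_s = t0, stop_s = t0 + e_half
          )
        }
        if (n_half > 0) {
          k <- k + 1L
          rows[[k]] <- list(
            trial_id = trials$trial_id[i], coder_id = coder_id,
            target = paste0(n_side, "_screen"),
            start_s = t0 + e_half, stop_s = t0 + e_half + n_half
          )
        }
      }
    }
    dplyr::bind_rows(rows[seq_len(k)])
  }

  seq_events <- function(trials) {
    if (nrow(trials) == 0) return(NULL)
    long <- tidyr::pivot_longer(
      trials[c("trial_id", paste0("look_", 1:6))],
      cols = -"trial_id", names_to = "position", names_prefix = "look_",
      values_to = "dur"
    )
    long$position <- as.integer(long$position)
    long <- long[!is.na(long$dur) & long$dur > 0, ]
    tibble(
      trial_id = long$trial_id,
      coder_id = coder_id,
      target = "screen",
      start_s = w3$start[long$position],
      stop_s = w3$start[long$position] + long$dur
    )
  }

  out <- dplyr::bind_rows(
    paired_events(study$exp1),
    paired_events(study$exp2),
    seq_events(study$exp3)
  )
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(
      trial_id = character(), coder_id = character(), target = character(),
      start_s = numeric(), stop_s = numeric()
    )
  }
  out
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits `subjects.csv`, `maternal.csv`, `trials_exp1.csv`, `trials_exp2.csv`,
#' `trials_exp3.csv`, plus the coded-event dialect (`events.csv`,
#' `manifest.csv`) that [read_looking_events()], [read_trial_manifest()] and
#' [assemble_trials()] consume, and the configuration as `config.csv`
#' (field/value pairs). The event files reproduce the trial looking times
#' exactly on re-assembly.
#'
#' @param study An `fb_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "fb_study")) stop_input("`study` must be an fb_study")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    subjects = file.path(dir, "subjects.csv"),
    maternal = file.path(dir, "maternal.csv"),
    exp1 = file.path(dir, "trials_exp1.csv"),
    exp2 = file.path(dir, "trials_exp2.csv"),
    exp3 = file.path(dir, "trials_exp3.csv"),
    events = file.path(dir, "events.csv"),
    manifest = file.path(dir, "manifest.csv"),
    config = file.path(dir, "config.csv")
  )
  readr::write_csv(study$subjects, paths["subjects"])
  readr::write_csv(study$maternal, paths["maternal"])
  readr::write_csv(study$exp1, paths["exp1"])
  readr::write_csv(study$exp2, paths["exp2"])
  readr::write_csv(study$exp3, paths["exp3"])
  readr::write_csv(build_events(study), paths["events"])
  readr::write_csv(build_manifest(study), paths["manifest"])
  cfg <- study$config
  cfg$age_curve <- NULL
  cfg_tbl <- tibble(
    field = c(names(cfg), "age_curve.juvenile_slope", "age_curve.plateau_age"),
    value = c(
      vapply(cfg, function(v) paste(format(v, digits = 17), collapse = ";"), character(1)),
      format(study$config$age_curve$juvenile_slope, digits = 17),
      format(study$config$age_curve$plateau_age, digits = 17)
    )
  )
  readr::write_csv(cfg_tbl, paths["config"])
  invisible(paths)
}

#' Read coded looking events
#'
#' Reads an interval-event table (`trial_id, coder_id, target, start_s,
#' stop_s`), validating the schema, target labels, that every event has
#' `stop_s > start_s`, and that events within one (trial, coder, target)
#' stream do not overlap. Malformed rows are reported by row number.
#'
#' @param path CSV file path.
#' @return Tibble of validated events.
#' @export
read_looking_events <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("Event file not found: %s", path))
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(ev, c("trial_id", "coder_id", "target", "start_s", "stop_s"),
                "Event table")
  validate_events(ev)
}

validate_events <- function(ev) {
  ev <- as_tibble(ev)
  bad_target <- which(!ev$target %in% EVENT_TARGETS)
  if (length(bad_target) > 0) {
    stop_input(sprintf(
      "Unknown target label in event row(s) %s",
      paste(head(bad_target, 5), collapse = ", ")
    ), class = "facebias_error_validation")
  }
  bad <- which(!(ev$stop_s > ev$start_s) | is.na(ev$start_s) | is.na(ev$stop_s))
  if (length(bad) > 0) {
    stop_input(sprintf(
      "Event stop_s must exceed start_s; offending row(s): %s",
      paste(head(bad, 5), collapse = ", ")
    ), class = "facebias_error_validation")
  }
  overlap <- ev |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$trial_id, .data$coder_id, .data$target) |>
    dplyr::arrange(.data$start_s, .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$start_s < dplyr::lag(.data$stop_s) - 1e-9) |>
    dplyr::ungroup()
  if (nrow(overlap) > 0) {
    stop_input(sprintf(
      "Overlapping events within a (trial, coder, target) stream; row(s): %s",
      paste(head(overlap$.row, 5), collapse = ", ")
    ), class = "facebias_error_validation")
  }
  ev
}

#' Read a trial manifest
#'
#' The manifest carries one row per trial: subject, experiment, trial-type
#' fields (expression / intensity / sequence and violating expression),
#' stimulus-window timings (`w1_start` ... up to `w6_stop`) and the side the
#' expression occupied in window 1 (sides swap between windows).
#'
#' @param path CSV file path.
#' @return Tibble of manifest rows.
#' @export
read_trial_manifest <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("Manifest file not found: %s", path))
  mf <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(
    mf,
    c("trial_id", "subject_id", "experiment", "n_windows",
      "w1_start", "w1_stop"),
    "Trial manifest"
  )
  if (anyDuplicated(mf$trial_id)) {
    stop_input("Duplicate trial_id in manifest", class = "facebias_error_validation")
  }
  mf
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory containing the study CSV files.
#' @return A list of class `fb_study` (without the original `config`).
#' @export
read_study <- function(dir) {
  rd <- function(f, types = NULL) {
    readr::read_csv(file.path(dir, f), show_col_types = FALSE, progress = FALSE,
                    col_types = types)
  }
  subjects <- rd("subjects.csv")
  subjects$sex <- factor(subjects$sex, levels = c("female", "male"))
  subjects$age_group <- factor(subjects$age_group, levels = c("adult", "juvenile"))
  subjects$mother_id <- as.character(subjects$mother_id)
  out <- list(
    config = NULL,
    subjects = subjects,
    maternal = rd("maternal.csv"),
    skills = NULL,
    exp1 = rd("trials_exp1.csv"),
    exp2 = rd("trials_exp2.csv"),
    exp3 = rd("trials_exp3.csv")
  )
  class(out) <- "fb_study"
  out
}
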