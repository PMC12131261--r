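# Assembling per-trial looking times from coded interval events and applying
# the trial inclusion criteria.

# Overlap of [start, stop] with [ws, we], truncating events at window edges
# (events straddling the black-screen gap are clipped, not reassigned).
window_overlap <- function(start, stop, ws, we) {
  pmax(0, pmin(stop, we) - pmax(start, ws))
}

#' Assemble per-trial looking times from coded events
#'
#' Sums event durations within each trial's stimulus windows (clipping events
#' at window edges) and attributes paired-trial durations to the expression
#' vs. the neutral image using the manifest's side assignment, with sides
#' swapped between the two presentation windows. Sequence trials get one
#' looking time per image position; a position never looked at is `NA`.
#' Events whose trial is missing from the manifest are an error; events
#' falling entirely outside every stimulus window are dropped with a message.
#'
#' @param events Validated events from [read_looking_events()].
#' @param manifest Manifest from [read_trial_manifest()].
#' @param coder One coder's stream to assemble (default: the first coder in
#'   the events; pass a `coder_id` to choose).
#' @return A list with tibbles `exp1`, `exp2`, `exp3` shaped like the
#'   generator output, covering every manifest trial (trials without events
#'   get zero/NA looks and `includable = FALSE`).
#' @export
assemble_trials <- function(events, manifest, coder = NULL) {
  events <- validate_events(events)
  check_columns(manifest, c("trial_id", "subject_id", "experiment", "n_windows"),
                "Trial manifest")

  if (is.null(coder)) coder <- events$coder_id[1]
  if (!is.null(coder) && nrow(events) > 0) {
    events <- events[events$coder_id == coder, ]
  }

  unknown <- setdiff(events$trial_id, manifest$trial_id)
  if (length(unknown) > 0) {
    stop_input(sprintf(
      "Events reference trial(s) absent from the manifest: %s",
      paste(head(unknown, 5), collapse = ", ")
    ), class = "facebias_error_validation")
  }

  ev <- dplyr::inner_join(events, manifest, by = "trial_id")
  max_w <- max(manifest$n_windows)
  ol <- matrix(0, nrow(ev), max_w)
  for (j in seq_len(max_w)) {
    ws <- ev[[paste0("w", j, "_start")]]
    we <- ev[[paste0("w", j, "_stop")]]
    use <- !is.na(ws) & j <= ev$n_windows
    ol[use, j] <- window_overlap(ev$start_s[use], ev$stop_s[use], ws[use], we[use])
  }
  outside <- nrow(ev) > 0 & rowSums(ol) == 0
  n_outside <- sum(outside)
  if (n_outside > 0) {
    message(n_outside, " event(s) fell outside every stimulus window and were dropped")
  }

  assemble_paired <- function(exp_label) {
    mf <- manifest[manifest$experiment == exp_label, ]
    if (nrow(mf) == 0) {
      return(if (exp_label == "exp1") empty_exp1() else empty_exp2())
    }
    sel <- ev$experiment == exp_label
    e <- ev[sel, ]
    eo <- ol[sel, , drop = FALSE]
    side_w1 <- e$expression_side_w1
    side_w2 <- ifelse(side_w1 == "left", "right", "left")
    expr_look <- eo[, 1] * (e$target == paste0(side_w1, "_screen")) +
      eo[, 2] * (e$target == paste0(side_w2, "_screen"))
    neut_look <- eo[, 1] * (e$target == paste0(side_w2, "_screen")) +
      eo[, 2] * (e$target == paste0(side_w1, "_screen"))
    agg <- tibble(trial_id = e$trial_id, expr = expr_look, neut = neut_look) |>
      dplyr::group_by(.data$trial_id) |>
      dplyr::summarise(
        look_expression_s = sum(.data$expr),
        look_neutral_s = sum(.data$neut)
      )
    out <- dplyr::left_join(mf, agg, by = "trial_id")
    out$look_expression_s[is.na(out$look_expression_s)] <- 0
    out$look_neutral_s[is.na(out$look_neutral_s)] <- 0
    out$includable <- out$look_expression_s > 0 & out$look_neutral_s > 0
    cols <- c("trial_id", "subject_id", "group_id",
              if (exp_label == "exp1") "expression" else "intensity",
              "stimulus_pair_id", "expression_side_w1",
              "look_expression_s", "look_neutral_s", "includable")
    out[intersect(cols, names(out))]
  }

  assemble_seq <- function() {
    mf <- manifest[manifest$experiment == "exp3", ]
    if (nrow(mf) == 0) return(empty_exp3())
    sel <- ev$experiment == "exp3" & ev$target == "screen"
    e <- ev[sel, ]
    eo <- ol[sel, , drop = FALSE]
    agg <- tibble(trial_id = e$trial_id)
    for (j in 1:6) agg[[paste0("look_", j)]] <- eo[, j]
    agg <- agg |>
      dplyr::group_by(.data$trial_id) |>
      dplyr::summarise(dplyr::across(dplyr::starts_with("look_"), sum))
    out <- dplyr::left_join(mf, agg, by = "trial_id")
    for (j in 1:6) {
      cl <- paste0("look_", j)
      out[[cl]][is.na(out[[cl]]) | out[[cl]] == 0] <- NA_real_
    }
    looks <- as.matrix(out[paste0("look_", 1:5)])
    out$includable <- rowSums(!is.na(looks)) >= 4 & !is.na(out$look_6)
    cols <- c("trial_id", "subject_id", "group_id", "sequence_expression",
              "violating_expression", paste0("look_", 1:6), "includable")
    out[intersect(cols, names(out))]
  }

  list(exp1 = assemble_paired("exp1"), exp2 = assemble_paired("exp2"),
       exp3 = assemble_seq())
}

#' Apply the trial inclusion criteria
#'
#' Paired (expression vs. neutral) trials are includable only if the subject
#' looked at both images; sequence trials only if at least four of the five
#' initial images and the final image were looked at. Returns the partition
#' with machine-readable exclusion reasons.
#'
#' @param trials A trial tibble from the generator or [assemble_trials()]
#'   (paired trials carry `look_expression_s`/`look_neutral_s`; sequence
#'   trials carry `look_1` ... `look_6`).
#' @return A list with `included`, `excluded` (with a `reason` column), and
#'   `n_excluded`.
#' @export
apply_inclusion <- function(trials) {
  trials <- as_tibble(trials)
  if (all(c("look_expression_s", "look_neutral_s") %in% names(trials))) {
    ok <- trials$look_expression_s > 0 & trials$look_neutral_s > 0
    reason <- ifelse(ok, NA_character_, "did_not_look_both")
  } else if (all(paste0("look_", 1:6) %in% names(trials))) {
    looks <- as.matrix(trials[paste0("look_", 1:5)])
    enough_initial <- rowSums(!is.na(looks) & looks > 0) >= 4
    has_final <- !is.na(trials$look_6) & trials$look_6 > 0
    ok <- enough_initial & has_final
    reason <- dplyr::case_when(
      ok ~ NA_character_,
      !has_final ~ "no_final_look",
      TRUE ~ "fewer_than_4_initial_looks"
    )
  } else {
    stop_input("`trials` has neither paired-trial nor sequence-trial columns",
               class = "facebias_error_schema")
  }
  excluded <- trials[!ok, , drop = FALSE]
  excluded$reason <- reason[!ok]
  included <- trials[ok, , drop = FALSE]
  included$includable <- TRUE
  list(included = included, excluded = excluded, n_excluded = nrow(excluded))
}
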