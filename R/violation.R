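# Violation-of-expectation analysis: extrapolate the habituation trend over
# the first five images and test the sixth-image excess.

#' Predict the sixth-image looking time from the first five
#'
#' Ordinary least squares of looking time on image position over the
#' positions that were looked at (at least four of the five required, the
#' inclusion rule), evaluated at position 6. Negative predictions are
#' returned as-is so the downstream paired test stays unbiased; callers can
#' flag them.
#'
#' @param times Numeric vector of length 5: looking seconds at images 1-5,
#'   `NA` where the image was not looked at.
#' @return The predicted looking time (seconds) at position 6.
#' @examples
#' predict_final_look(c(2.0, 1.8, 1.6, 1.4, 1.2)) # exactly 1.0
#' predict_final_look(c(1, 2, 1, 2, 1)) # 1.4 (flat fit at the mean)
#' @export
predict_final_look <- function(times) {
  if (length(times) != 5) {
    stop_input("`times` must have length 5 (positions 1-5)",
               class = "facebias_error_precondition")
  }
  pos <- which(!is.na(times))
  if (length(pos) < 4) {
    stop_input("Need at least 4 of 5 initial looking times",
               class = "facebias_error_precondition")
  }
  y <- times[pos]
  xbar <- mean(pos)
  ybar <- mean(y)
  slope <- sum((pos - xbar) * (y - ybar)) / sum((pos - xbar)^2)
  ybar + slope * (6 - xbar)
}

#' Score whether the observed final look exceeds the prediction
#'
#' Binary response: 1 iff the observed sixth-image looking time is strictly
#' higher than the trend-predicted one (a tie scores 0).
#'
#' @param observed_s,predicted_s Observed and predicted sixth-image looking
#'   times (seconds); vectorised.
#' @return Integer vector of 0/1.
#' @export
violation_binary <- function(observed_s, predicted_s) {
  as.integer(observed_s > predicted_s)
}

#' Build per-trial violation records
#'
#' For every includable sequence trial, fits the habituation line on the
#' present initial looks, predicts the sixth-image looking time, and scores
#' the excess.
#'
#' @param trials Sequence-trial tibble (`look_1` ... `look_6`, `includable`).
#' @return Tibble with the trial reference columns plus `predicted_s`,
#'   `observed_s`, `excess_s`, `exceeds` (0/1), and `negative_prediction`.
#' @export
violation_records <- function(trials) {
  check_columns(trials, c(paste0("look_", 1:6), "includable"), "Sequence trials")
  out <- dplyr::filter(as_tibble(trials), .data$includable)
  looks <- as.matrix(out[paste0("look_", 1:5)])
  out$predicted_s <- apply(looks, 1, predict_final_look)
  out$observed_s <- out$look_6
  out$excess_s <- out$observed_s - out$predicted_s
  out$exceeds <- violation_binary(out$observed_s, out$predicted_s)
  out$negative_prediction <- out$predicted_s < 0
  out
}

#' Paired t-test of observed vs. predicted final looking times
#'
#' Two-sided paired t-test across trials of the observed sixth-image looking
#' time against the trend-predicted one; a significant positive mean excess
#' indicates looking longer at the sequence-violating expression than the
#' habituation trend predicts.
#'
#' @param records Tibble from [violation_records()].
#' @return One-row tibble: `estimate` (mean excess, s), `statistic` (t),
#'   `df`, `p.value`, `conf.low`, `conf.high`, `n`.
#' @export
violation_test <- function(records) {
  check_columns(records, c("observed_s", "predicted_s"), "Violation records")
  ok <- !is.na(records$observed_s) & !is.na(records$predicted_s)
  obs <- records$observed_s[ok]
  pred <- records$predicted_s[ok]
  if (length(obs) < 2) {
    stop_input("Need at least 2 trials for the paired test",
               class = "facebias_error_degenerate")
  }
  tt <- t.test(obs, pred, paired = TRUE)
  tibble(
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    conf.low = tt$conf.int[1],
    conf.high = tt$conf.int[2],
    n = length(obs)
  )
}
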