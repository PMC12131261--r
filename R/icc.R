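# Inter-coder reliability: two-way random-effects intraclass correlation,
# average measures, from the two-way ANOVA mean squares (McGraw & Wong).

#' Intraclass correlation for inter-coder reliability
#'
#' Computes the average-measures intraclass correlation across coders from a
#' long table of duration measurements on common units (e.g. two coders'
#' total looking times on the same videos). The default is the two-way
#' random-effects, absolute-agreement, average-measures form (ICC(A,k),
#' a.k.a. ICC(2,k)), with the Satterthwaite-style F confidence interval;
#' `type = "consistency"` gives ICC(C,k) (ICC(3,k)) instead. The p-value
#' tests ICC = 0 via F = MSR/MSE on (n - 1, (n - 1)(k - 1)) df.
#'
#' @param data Long tibble of ratings.
#' @param unit,coder,value Names of the columns identifying the rated unit,
#'   the coder, and the measurement.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return One-row tibble: `type`, `icc`, `ci_lower`, `ci_upper`,
#'   `statistic` (F), `df1`, `df2`, `p.value`, `n_units`, `n_coders`.
#' @examples
#' ratings <- tibble::tibble(
#'   unit = rep(1:3, each = 2),
#'   coder = rep(c("a", "b"), 3),
#'   value = c(4, 4, 2, 2, 6, 6)
#' )
#' icc(ratings) # perfect agreement: ICC = 1
#' @export
icc <- function(data, unit = "unit", coder = "coder", value = "value",
                type = c("agreement", "consistency"), conf_level = 0.95) {
  type <- match.arg(type)
  check_columns(data, c(unit, coder, value), "ICC ratings table")

  wide <- tidyr::pivot_wider(
    data[c(unit, coder, value)],
    names_from = dplyr::all_of(coder), values_from = dplyr::all_of(value)
  )
  x <- as.matrix(wide[, -1, drop = FALSE])
  incomplete <- rowSums(is.na(x)) > 0
  if (any(incomplete)) {
    warn(sprintf("Dropping %d unit(s) not rated by every coder", sum(incomplete)))
    x <- x[!incomplete, , drop = FALSE]
  }
  n <- nrow(x)
  k <- ncol(x)
  if (k < 2) stop_input("ICC needs at least 2 coders", class = "facebias_error_degenerate")
  if (n < 2) stop_input("ICC needs at least 2 complete units", class = "facebias_error_degenerate")

  grand <- mean(x)
  rowm <- rowMeans(x)
  colm <- colMeans(x)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  resid <- sweep(sweep(x, 1, rowm), 2, colm) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))

  if (msr <= 0) {
    stop_input("Ratings are constant across units; ICC is undefined",
               class = "facebias_error_degenerate")
  }

  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  alpha <- 1 - conf_level

  if (mse < 1e-12 * msr) {
    # Perfect agreement within rounding: coders identical on every unit.
    return(tibble(
      type = type, icc = 1, ci_lower = 1, ci_upper = 1,
      statistic = Inf, df1 = df1, df2 = df2, p.value = 0,
      n_units = n, n_coders = k
    ))
  }

  fstat <- msr / mse
  p <- pf(fstat, df1, df2, lower.tail = FALSE)

  if (type == "consistency") {
    est <- (msr - mse) / msr
    fl <- fstat / qf(1 - alpha / 2, df1, df2)
    fu <- fstat * qf(1 - alpha / 2, df2, df1)
    lo <- 1 - 1 / fl
    hi <- 1 - 1 / fu
  } else {
    est <- (msr - mse) / (msr + (msc - mse) / n)
    # Single-measures agreement ICC and its Satterthwaite df drive the CI;
    # average-measures bounds follow by Spearman-Brown.
    icc_a1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    fj <- msc / mse
    vn <- df2 * (k * icc_a1 * fj + n * (1 + (k - 1) * icc_a1) - k * icc_a1)^2
    vd <- df1 * k^2 * icc_a1^2 * fj^2 + (n * (1 + (k - 1) * icc_a1) - k * icc_a1)^2
    v <- vn / vd
    f2u <- qf(1 - alpha / 2, df1, v)
    f2l <- qf(1 - alpha / 2, v, df1)
    l1 <- n * (msr - f2u * mse) /
      (f2u * (k * msc + (k * n - k - n) * mse) + n * msr)
    u1 <- n * (f2l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2l * msr)
    lo <- l1 * k / (1 + l1 * (k - 1))
    hi <- u1 * k / (1 + u1 * (k - 1))
  }

  tibble(
    type = type, icc = est, ci_lower = lo, ci_upper = hi,
    statistic = fstat, df1 = df1, df2 = df2, p.value = p,
    n_units = n, n_coders = k
  )
}
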