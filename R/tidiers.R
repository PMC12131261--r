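# broom-style methods and printing for fitted objects.

#' Tidy a facebias mixed model
#'
#' @param x An `fb_lmm`.
#' @param effects `"fixed"` (coefficient table with Satterthwaite df) or
#'   `"ran_pars"` (random-effect variances and SDs).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fb_lmm
#' @export
tidy.fb_lmm <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$coefficients else x$varcor
}

#' One-row model summary for a facebias mixed model
#'
#' @param x An `fb_lmm`.
#' @param ... Unused.
#' @return Tibble with `nobs`, `sigma`, `logLik`, `AIC`, `BIC`, `REML`,
#'   `singular`.
#' @method glance fb_lmm
#' @export
glance.fb_lmm <- function(x, ...) {
  tibble(
    nobs = x$nobs,
    sigma = stats::sigma(x$fit),
    logLik = as.numeric(logLik(x$fit)),
    AIC = AIC(x$fit),
    BIC = BIC(x$fit),
    REML = x$REML,
    singular = x$singular
  )
}

#' @export
print.fb_lmm <- function(x, ...) {
  cat("<fb_lmm> ", deparse(x$formula), "\n", sep = "")
  cat("  ", x$nobs, " observations; ",
      if (x$REML) "REML" else "ML",
      if (x$singular) "; singular fit" else "", "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Tidy an age-model suite
#'
#' @param x An `fb_age_suite`.
#' @param ... Unused.
#' @return Fixed-effect tables of the four models, stacked with a `model`
#'   column.
#' @method tidy fb_age_suite
#' @export
tidy.fb_age_suite <- function(x, ...) {
  dplyr::bind_rows(lapply(x, function(m) m$coefficients), .id = "model")
}

#' @export
print.fb_age_suite <- function(x, ...) {
  cat("<fb_age_suite> models:", paste(names(x), collapse = ", "), "\n")
  print(tidy(x))
  invisible(x)
}
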