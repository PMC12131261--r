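# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated-normal draws by inverse-CDF; lo/hi may be -Inf/Inf.
# Vectorised over mean.
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  u <- runif(n, plo, phi)
  qnorm(u, mean, sd)
}

#' @importFrom stats pnorm
NULL

# Beta-binomial draws with mean probability `mu` and precision `phi`
# (variance of the latent p is mu(1-mu)/(1+phi)).
rbetabinom <- function(n, size, mu, phi) {
  p <- rbeta(n, mu * phi, (1 - mu) * phi)
  rbinom(n, size, p)
}

stop_config <- function(msg, field = NULL) {
  abort(msg, class = "facebias_error_config", field = field)
}

stop_input <- function(msg, class = "facebias_error_input") {
  abort(msg, class = class)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "%s is missing required column%s: %s",
        what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      class = "facebias_error_schema"
    )
  }
  invisible(df)
}
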