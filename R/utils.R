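# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Raise a classed condition so callers can distinguish error families.
stop_leafpol <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "leafpol_error", "error")))
}

stop_dim <- function(msg) stop_leafpol(msg, "leafpol_dimension_error")
stop_param <- function(msg) stop_leafpol(msg, "leafpol_parameter_error")
stop_geom <- function(msg) stop_leafpol(msg, "leafpol_geometry_error")
stop_format <- function(msg) stop_leafpol(msg, "leafpol_format_error")
stop_fit <- function(msg) stop_leafpol(msg, "leafpol_fit_error")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every generator is a pure function of (spec, seed) through this helper.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_param("`seed` must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp_index <- function(i, n) pmin.int(pmax.int(i, 1L), n)

# Check a numeric scalar
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0) stop_param(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) stop_param(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

# Sample n draws from N(mu, Sigma) via the Cholesky factor (2-D use here).
rmvnorm_chol <- function(n, mu, sigma) {
  p <- length(mu)
  L <- tryCatch(chol(sigma), error = function(e)
    stop_param("covariance matrix is not positive-definite"))
  z <- matrix(stats::rnorm(n * p), n, p) %*% L
  sweep(z, 2L, mu, "+")
}
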