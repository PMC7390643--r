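# Internal helpers shared across modules.

#' Evaluate an expression with a local, seeded RNG state
#'
#' Saves and restores `.Random.seed` so seeded simulators never disturb the
#' caller's RNG stream. A `NULL` seed runs on the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Unit-mean lognormal multiplicative noise
#'
#' Lognormal with sd of log `sigma` and meanlog `-sigma^2/2`, so the noise has
#' expectation exactly 1 and does not bias channel totals.
#' @noRd
rlnorm_unit <- function(n, sigma) {
  if (sigma <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' @noRd
assert_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("'%s' = %g outside [%g, %g]", name, x, min, max), call. = FALSE)
  invisible(x)
}

#' Derive a per-task sub-seed from a base seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @noRd
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
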