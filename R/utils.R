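## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Run an expression under a local, seeded RNG state
#'
#' All stochastic operations in the package accept an integer seed and are
#' reproducible; the caller's global RNG state is restored on exit.
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("%s must be positive and finite", name)
  invisible(x)
}

## log of the Dirichlet density at x (simplex point) with parameter alpha
ldirichlet <- function(x, alpha) {
  if (any(x <= 0) || any(alpha <= 0)) return(-Inf)
  sum((alpha - 1) * log(x)) - sum(lgamma(alpha)) + lgamma(sum(alpha))
}
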