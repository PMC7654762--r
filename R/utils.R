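# Internal helpers shared across the package.

# Run `expr` under a temporary RNG state seeded with `seed`; restore the
# caller's state afterwards. A NULL seed leaves the global stream untouched
# (nondeterministic by design).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Wrap angles into (-pi, pi].
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper),
         call. = FALSE)
  invisible(x)
}

# Inverse error function via the normal quantile.
erfinv <- function(x) stats::qnorm((x + 1) / 2) / sqrt(2)

# next power of two >= n (for FFT sizes)
next_pow2 <- function(n) 2^ceiling(log2(max(n, 1)))

`%||%` <- function(a, b) if (is.null(a)) b else a
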