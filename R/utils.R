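# internal helpers shared across modules

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

check_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE,
                             finite = TRUE) {
  abort_if(!is.numeric(x) || length(x) != 1L || is.na(x),
           sprintf("'%s' must be a single non-missing number", name))
  abort_if(finite && !is.finite(x), sprintf("'%s' must be finite", name))
  abort_if(positive && x <= 0, sprintf("'%s' must be strictly positive", name))
  abort_if(nonneg && x < 0, sprintf("'%s' must be non-negative", name))
  invisible(x)
}

# Run code with a temporary RNG state seeded by `seed`; the caller's
# .Random.seed is restored on exit so generators never leak randomness.
with_seed <- function(seed, code) {
  abort_if(is.null(seed) || is.na(seed), "a seed is mandatory")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Central-difference Jacobian of f: R^n -> R^m at x.
num_jacobian <- function(f, x, eps = NULL) {
  n <- length(x)
  f0 <- f(x)
  m <- length(f0)
  J <- matrix(0, m, n)
  if (is.null(eps)) eps <- pmax(abs(x), 1) * sqrt(.Machine$double.eps)
  for (j in seq_len(n)) {
    xp <- x; xm <- x
    xp[j] <- x[j] + eps[j]
    xm[j] <- max(x[j] - eps[j], 0)
    hj <- xp[j] - xm[j]
    J[, j] <- (f(xp) - f(xm)) / hj
  }
  J
}

`%||%` <- function(a, b) if (is.null(a)) b else a
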