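# Steady-state machinery: adaptive explicit Runge-Kutta integration to
# quasi-equilibrium followed by damped-Newton root polishing.  The circuit
# models here are low-dimensional (3-5 species) and only mildly stiff (the
# fastest eigenvalue is set by the protease binding step), so an embedded
# RK pair with step-size control is adequate and keeps the package free of
# compiled dependencies.

# Dormand-Prince 5(4) coefficients
.dp_A <- list(
  c(1/5),
  c(3/40, 9/40),
  c(44/45, -56/15, 32/9),
  c(19372/6561, -25360/2187, 64448/6561, -212/729),
  c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
  c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)
)
.dp_b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
.dp_b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)

# Integrate y' = f(y) from 0 to t_end with adaptive steps; states are
# projected onto the non-negative orthant after each accepted step (the
# models are positively invariant, so projection only removes round-off
# undershoot).  Stops early if max|f| falls below `stop_resid`.
rk45_integrate <- function(f, y0, t_end, rtol = 1e-7, atol = 1e-12,
                           stop_resid = 0, max_steps = 500000L) {
  y <- y0
  t <- 0
  f0 <- f(y)
  h <- min(t_end / 100, 1e-3)
  nstep <- 0L
  while (t < t_end && nstep < max_steps) {
    h <- min(h, t_end - t)
    ks <- matrix(0, length(y), 7L)
    ks[, 1L] <- f0
    for (i in 1:6) {
      yi <- y + h * as.vector(ks[, seq_along(.dp_A[[i]]), drop = FALSE] %*%
                                .dp_A[[i]])
      ks[, i + 1L] <- f(pmax(yi, 0))
    }
    y5 <- y + h * as.vector(ks %*% .dp_b5)
    y4 <- y + h * as.vector(ks %*% .dp_b4)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (is.finite(err) && err <= 1) {
      t <- t + h
      y <- pmax(y5, 0)
      f0 <- ks[, 7L]          # FSAL property of Dormand-Prince
      if (any(y5 < 0)) f0 <- f(y)
      if (stop_resid > 0 && max(abs(f0)) <= stop_resid) break
    } else {
      f0 <- f(y)              # re-evaluate at current point after rejection
    }
    fac <- if (is.finite(err) && err > 0) 0.9 * err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
    nstep <- nstep + 1L
  }
  list(y = y, t = t, steps = nstep)
}

# Damped Newton iteration on f(y) = 0 with numerical Jacobian, constrained
# to the non-negative orthant.
newton_polish <- function(f, y0, tol_abs, max_iter = 50L) {
  y <- y0
  res <- max(abs(f(y)))
  for (it in seq_len(max_iter)) {
    if (res <= tol_abs) break
    J <- num_jacobian(f, y)
    step <- tryCatch(solve(J, -f(y)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    improved <- FALSE
    for (half in 1:20) {
      y_new <- pmax(y + lambda * step, 0)
      r_new <- max(abs(f(y_new)))
      if (is.finite(r_new) && r_new < res) {
        y <- y_new; res <- r_new; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  list(y = y, residual = res)
}

#' Solve a circuit model to steady state
#'
#' Integrates the system to quasi-equilibrium with an adaptive embedded
#' Runge-Kutta scheme, then polishes the state by damped Newton root
#' finding on the right-hand side.  Convergence is declared on the maximum
#' absolute time-derivative relative to the model's production scale (the
#' right-hand side evaluated at the zero state, i.e. the pure production
#' fluxes), so the tolerance is dimensionless.  By default the solve is
#' repeated from a second, distinct non-negative initialization and the two
#' states are required to agree, guarding against multistability going
#' unnoticed.
#'
#' @param rhs function of a single argument (the state vector) returning the
#'   time derivatives; build one from [merger_rhs()] or [full_rhs()] with a
#'   closure, e.g. `function(s) merger_rhs(s, p, u, R)`.
#' @param init non-negative initial state (named vector; names are carried
#'   through to the result).
#' @param tol convergence tolerance on `max|dy/dt|` relative to the
#'   production scale.
#' @param t_max integration horizon (hr).  Non-convergence within `t_max`
#'   yields `converged = FALSE`, never an error.
#' @param check_unique verify the fixed point from a second initialization
#'   (doubles the cost); the relative state difference must be below
#'   `10 * tol`.
#' @param second_init optional alternative initialization for the
#'   uniqueness check; by default a state displaced to the production scale.
#' @return An object of class `steady_state_result`: `state`, `converged`,
#'   `residual_norm` (relative), `method` (`"integration+root"`), `t_used`,
#'   and `unique` (`NA` when the check is skipped).
#' @examples
#' # pure birth-death: dP/dt = 2 - P  =>  P* = 2
#' ss <- solve_steady_state(function(s) c(P = 2 - s[[1]]), init = c(P = 0))
#' ss$state
#' @export
solve_steady_state <- function(rhs, init, tol = 1e-9, t_max = 200,
                               check_unique = TRUE, second_init = NULL) {
  check_scalar_num(tol, "tol", positive = TRUE)
  check_scalar_num(t_max, "t_max", positive = TRUE)
  abort_if(any(init < 0), "initial state must be non-negative")
  nm <- names(init)
  f <- function(y) as.numeric(rhs(y))
  prod_scale <- max(abs(f(numeric(length(init)))))
  if (!is.finite(prod_scale) || prod_scale <= 0) prod_scale <- 1
  tol_abs <- tol * prod_scale

  # Integrate in growing chunks and attempt a Newton polish after each one;
  # accepting the polished state only when it meets the tolerance keeps the
  # root finder from committing to a spurious point far from equilibrium.
  solve_once <- function(y0) {
    y <- as.numeric(y0)
    t_done <- 0
    targets <- unique(c(pmin(t_max / 40 * 2^(0:20), t_max)))
    for (tt in targets) {
      intg <- rk45_integrate(f, y, t_end = tt - t_done, stop_resid = tol_abs)
      y <- intg$y
      t_done <- t_done + intg$t
      pol <- newton_polish(f, y, tol_abs = tol_abs * 1e-3)
      if (pol$residual <= tol_abs)
        return(list(y = pol$y, residual = pol$residual, t = t_done))
      res_y <- max(abs(f(y)))
      if (res_y <= tol_abs)
        return(list(y = y, residual = res_y, t = t_done))
      if (tt >= t_max) break
    }
    res_y <- max(abs(f(y)))
    if (pol$residual < res_y) list(y = pol$y, residual = pol$residual, t = t_done)
    else list(y = y, residual = res_y, t = t_done)
  }

  s1 <- solve_once(init)
  unique_ok <- NA
  if (check_unique) {
    alt <- second_init %||% (as.numeric(init) + pmax(prod_scale, 1))
    alt <- pmax(as.numeric(alt), 0)
    s2 <- solve_once(alt)
    denom <- pmax(abs(s1$y), abs(s2$y), prod_scale * .Machine$double.eps)
    unique_ok <- max(abs(s1$y - s2$y) / denom) <= 10 * tol
  }
  state <- s1$y
  names(state) <- nm
  structure(list(state = state,
                 converged = s1$residual <= tol_abs,
                 residual_norm = s1$residual / prod_scale,
                 method = "integration+root",
                 t_used = s1$t,
                 unique = unique_ok),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("Steady state (%s): %s, relative residual %.3g\n",
              x$method,
              if (x$converged) "converged" else "NOT converged",
              x$residual_norm))
  print(x$state)
  if (!is.na(x$unique) && !x$unique)
    cat("warning: second initialization reached a different state\n")
  invisible(x)
}
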