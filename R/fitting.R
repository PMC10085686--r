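# Nonlinear least squares on replicate-mean dose-response data, with
# bounded log-uniform multistart and linearized (Jacobian) 95% intervals.
# Optimization runs in log10 parameter space (all model parameters are
# positive scale parameters), which makes the bounded search well
# conditioned; intervals are computed on the natural scale.

nls_multistart <- function(d, fn, lower, upper, n_starts = 10L, seed = 1L) {
  y <- d$output
  ssr <- function(logp) {
    r <- y - fn(10^logp, d)
    if (any(!is.finite(r))) return(.Machine$double.xmax)
    sum(r^2)
  }
  llo <- log10(lower); lup <- log10(upper)
  starts <- with_seed(seed, {
    s <- matrix(stats::runif(n_starts * length(lower)), n_starts)
    sweep(sweep(s, 2, lup - llo, "*"), 2, llo, "+")
  })
  starts[1, ] <- (llo + lup) / 2           # one deterministic central start
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- stats::setNames(starts[i, ], names(lower))
    opt <- tryCatch(
      stats::optim(par0, ssr, method = "L-BFGS-B",
                   lower = llo, upper = lup,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  abort_if(is.null(best), "all optimizer starts failed")
  est <- 10^best$par
  names(est) <- names(lower)
  conv <- is.finite(best$value) && best$value < .Machine$double.xmax
  # Linearized covariance on the natural scale.  Residual variance on
  # dose-response readouts is multiplicative (grows with the mean), so the
  # interval uses the heteroskedasticity-consistent sandwich estimator with
  # the HC3 leverage correction (the classical homoskedastic covariance
  # undercovers badly under lognormal noise; plain HC0/HC1 still undercover
  # at replicate-mean sample sizes because the high-signal points carry the
  # leverage).
  ci <- NULL
  if (conv) {
    J <- num_jacobian(function(p) fn(p, d), est)
    e <- y - fn(est, d)
    dof <- max(length(y) - length(est), 1L)
    bread <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(bread)) {
      h <- pmin(rowSums((J %*% bread) * J), 1 - 1e-8)
      meat <- crossprod(J * (e / (1 - h)))     # J' diag(e^2/(1-h)^2) J
      cov <- bread %*% meat %*% bread
      se <- sqrt(pmax(diag(cov), 0))
      tq <- stats::qt(0.975, dof)
      ci <- cbind(lower = est - tq * se, upper = est + tq * se)
      rownames(ci) <- names(est)
    }
  }
  list(estimates = est, residual_sum = best$value, ci95 = ci,
       converged = conv && !is.null(ci), n_starts = n_starts)
}

make_fit_result <- function(nls, d, fn, flags = list()) {
  pred <- fn(nls$estimates, d)
  r2 <- goodness_of_fit_values(d$output, pred)
  structure(c(nls, list(r_squared = r2, flags = flags)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s): %s, SSR = %.6g, R^2 = %.5f\n",
              paste(names(x$estimates), collapse = ", "),
              if (x$converged) "converged" else "NOT converged",
              x$residual_sum, x$r_squared))
  for (nm in names(x$estimates)) {
    ci <- if (!is.null(x$ci95)) sprintf(" [%.6g, %.6g]", x$ci95[nm, 1],
                                        x$ci95[nm, 2]) else ""
    cat(sprintf("  %s = %.6g%s\n", nm, x$estimates[nm], ci))
  }
  for (nm in names(x$flags))
    if (!isTRUE(x$flags[[nm]])) cat(sprintf("  flag: %s = %s\n", nm,
                                            x$flags[[nm]]))
  invisible(x)
}

#' Fit the reduced merger law to a dose-response table
#'
#' Estimates the ratiometric sensitivity `c` of `output = c * Y/X` by
#' bounded multistart nonlinear least squares on replicate means.
#'
#' @param t a [dose_response_table()] with `X > 0` everywhere and at least 3
#'   distinct conditions.
#' @param bounds length-2 positive bounds on `c`; defaults are derived from
#'   the data range.
#' @param n_starts number of multistart attempts.
#' @param seed RNG seed for the start draws (deterministic fits).
#' @return A `fit_result` with estimate `c`.
#' @export
fit_reduced_merger <- function(t, bounds = NULL, n_starts = 10L, seed = 1L) {
  stopifnot(inherits(t, "dose_response_table"))
  abort_if(any(t$X_uM <= 0), "all rows must have X > 0")
  d <- replicate_means(t)
  abort_if(nrow(d) < 3L, "need at least 3 distinct conditions")
  abort_if(all(d$Y_uM == 0),
           "degenerate design: c is unidentifiable when all Y = 0")
  if (is.null(bounds)) {
    scale <- max(d$output, na.rm = TRUE) /
      max(d$Y_uM[d$Y_uM > 0] / d$X_uM[d$Y_uM > 0])
    bounds <- c(scale * 1e-4, scale * 1e4)
  }
  fn <- function(p, d) p[[1]] * d$Y_uM / d$X_uM
  nls <- nls_multistart(d, fn, lower = c(c = bounds[1]),
                        upper = c(c = bounds[2]),
                        n_starts = n_starts, seed = seed)
  make_fit_result(nls, d, fn)
}

#' Fit the broken-merging law to a dose-response table
#'
#' Estimates `(amplitude, c1, c2)` of
#' `output = amplitude * c2*Y / (1 + c1*X + c2*Y)` (the amplitude is
#' `k6 * R_tot / gamma` in circuit terms) by bounded multistart nonlinear
#' least squares on replicate means.  The saturation constant `c2` is only
#' identifiable when the data span both the linear and the saturating `Y`
#' regime; otherwise the result carries
#' `flags$saturation_identifiable = FALSE`.
#'
#' @inheritParams fit_reduced_merger
#' @param fixed named list of parameters to hold fixed (e.g.
#'   `list(amplitude = 1e5, c2 = 0.1)` to recover `c1` from X-only designs).
#' @return A `fit_result` with estimates among `amplitude`, `c1`, `c2`.
#' @export
fit_broken_merging <- function(t, fixed = list(), n_starts = 10L, seed = 1L) {
  stopifnot(inherits(t, "dose_response_table"))
  abort_if(any(t$X_uM <= 0), "all rows must have X > 0")
  d <- replicate_means(t)
  abort_if(nrow(d) < 3L, "need at least 3 distinct conditions")
  abort_if(all(d$Y_uM == 0), "degenerate design: all Y = 0")
  out_max <- max(d$output, na.rm = TRUE)
  lower <- c(amplitude = out_max * 1e-2, c1 = 1e-8, c2 = 1e-8)
  upper <- c(amplitude = out_max * 1e4, c1 = 1e2, c2 = 1e2)
  free <- setdiff(names(lower), names(fixed))
  abort_if(length(free) == 0, "no free parameters")
  model_all <- function(p, d)
    p[["amplitude"]] * p[["c2"]] * d$Y_uM /
      (1 + p[["c1"]] * d$X_uM + p[["c2"]] * d$Y_uM)
  fn <- function(p, d) {
    full <- c(as.list(p), fixed)
    model_all(full, d)
  }
  nls <- nls_multistart(d, fn, lower = lower[free], upper = upper[free],
                        n_starts = n_starts, seed = seed)
  c2_hat <- if ("c2" %in% free) nls$estimates[["c2"]] else fixed$c2
  sat <- c2_hat * max(d$Y_uM) > 0.1
  if (!is.null(nls$ci95) && "c2" %in% rownames(nls$ci95)) {
    ci <- nls$ci95["c2", ]
    if (ci[1] <= 0 || ci[2] / max(ci[1], 1e-300) > 1e2) sat <- FALSE
  }
  make_fit_result(nls, d, fn,
                  flags = list(saturation_identifiable = sat))
}

goodness_of_fit_values <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    r2 <- NA_real_
    attr(r2, "degenerate") <- TRUE
    return(r2)
  }
  r2 <- 1 - sum((obs - pred)^2) / ss_tot
  attr(r2, "degenerate") <- FALSE
  r2
}

#' Coefficient of determination on replicate means
#'
#' `R^2 = 1 - SS_res / SS_tot` of the supplied predictions against the
#' replicate-mean outputs of the table (conditions ordered by `X`, then
#' `Y`).  A table with zero output variance is degenerate: `NA` with
#' attribute `degenerate = TRUE`.
#'
#' @param t a [dose_response_table()].
#' @param predictions predicted outputs, one per distinct condition in
#'   (X, Y) order.
#' @return Numeric `R^2` with attribute `degenerate`.
#' @export
goodness_of_fit <- function(t, predictions) {
  stopifnot(inherits(t, "dose_response_table"))
  d <- replicate_means(t)
  abort_if(length(predictions) != nrow(d),
           sprintf("expected %d predictions (one per condition), got %d",
                   nrow(d), length(predictions)))
  goodness_of_fit_values(d$output, predictions)
}
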