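#' Dose-response table
#'
#' The shared container for measured, simulated and synthetic steady-state
#' readouts: one row per (X, Y, replicate) with a non-negative output in
#' GFP/OD units.  Rows whose model evaluation failed carry `NA` output and
#' are counted in the `n_failed` attribute rather than aborting a sweep.
#'
#' @param X,Y inducer concentrations (uM).
#' @param replicate replicate index (integer).
#' @param output steady-state readout (GFP/OD); `NA` marks a failed row.
#' @param metadata named list recorded alongside the data (model tag, TIR,
#'   aTc, noise spec, seed, ...).
#' @return A `data.frame` of class `dose_response_table` with columns
#'   `X_uM`, `Y_uM`, `replicate`, `output`.
#' @export
dose_response_table <- function(X, Y, replicate = 1L, output,
                                metadata = list()) {
  df <- data.frame(X_uM = as.numeric(X), Y_uM = as.numeric(Y),
                   replicate = as.integer(replicate),
                   output = as.numeric(output))
  abort_if(any(df$X_uM < 0) || any(df$Y_uM < 0),
           "inducer concentrations must be non-negative")
  abort_if(any(df$output < 0, na.rm = TRUE), "outputs must be non-negative")
  key <- paste(df$X_uM, df$Y_uM, df$replicate)
  dup <- duplicated(key)
  abort_if(any(dup), sprintf("duplicate (X, Y, replicate) keys in rows: %s",
                             paste(which(dup), collapse = ", ")))
  attr(df, "metadata") <- metadata
  attr(df, "n_failed") <- sum(is.na(df$output))
  class(df) <- c("dose_response_table", "data.frame")
  df
}

# replicate means over conditions, dropping failed rows
replicate_means <- function(t) {
  ok <- !is.na(t$output)
  agg <- stats::aggregate(output ~ X_uM + Y_uM, data = t[ok, , drop = FALSE],
                          FUN = mean)
  agg[order(agg$X_uM, agg$Y_uM), , drop = FALSE]
}

#' Sweep a steady-state model over an inducer grid
#'
#' Evaluates `model(X, Y)` at every point of the Cartesian grid.  A model
#' failure (error or non-convergence) at a point flags that row with `NA`
#' and the sweep continues; the total failure count is reported in the
#' table's `n_failed` attribute.
#'
#' @param model function of `(X, Y)` returning a scalar steady-state output.
#' @param X_grid,Y_grid inducer grids (uM), non-empty.
#' @param metadata extra metadata stored on the result.
#' @return A [dose_response_table()] with `replicate = 1`.
#' @export
dose_response_sweep <- function(model, X_grid, Y_grid, metadata = list()) {
  abort_if(length(X_grid) == 0 || length(Y_grid) == 0,
           "grids must be non-empty")
  pts <- expand.grid(X_uM = X_grid, Y_uM = Y_grid)
  out <- vapply(seq_len(nrow(pts)), function(i) {
    tryCatch(as.numeric(model(pts$X_uM[i], pts$Y_uM[i])),
             error = function(e) NA_real_)
  }, numeric(1))
  dose_response_table(pts$X_uM, pts$Y_uM, 1L, out,
                      metadata = c(metadata, list(kind = "sweep")))
}

#' Linear fit of output against the input ratio
#'
#' Ordinary least squares of the replicate-mean output against `Y/X`.  The
#' intercept-included fit is canonical; a through-origin slope is reported
#' alongside.  A table with zero output variance is degenerate: slope 0 and
#' `r_squared = 0` are returned with `degenerate = TRUE`.
#'
#' @param t a [dose_response_table()] with `X > 0` everywhere and at least 3
#'   distinct ratios.
#' @param per_replicate fit on replicate-resolved rows instead of replicate
#'   means.
#' @return An object of class `linear_ratio_fit`: `slope`, `intercept`,
#'   `r_squared`, `slope_origin`, `slope_se`, `n`, `degenerate`.
#' @export
ratio_response_fit <- function(t, per_replicate = FALSE) {
  stopifnot(inherits(t, "dose_response_table"))
  abort_if(any(t$X_uM <= 0), "ratio undefined: all rows must have X > 0")
  d <- if (per_replicate) data.frame(X_uM = t$X_uM, Y_uM = t$Y_uM,
                                     output = t$output)[!is.na(t$output), ]
       else replicate_means(t)
  ratio <- d$Y_uM / d$X_uM
  abort_if(length(unique(ratio)) < 3L, "need at least 3 distinct ratios")
  y <- d$output
  if (stats::var(y) == 0) {
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0,
                          slope_origin = 0, slope_se = NA_real_,
                          n = length(y), degenerate = TRUE),
                     class = "linear_ratio_fit"))
  }
  fit <- stats::lm(y ~ ratio)
  # noiseless model-generated tables fit exactly; summary.lm warns about the
  # zero residual variance, which is expected here rather than suspicious
  sm <- suppressWarnings(summary(fit))
  fit0 <- stats::lm(y ~ ratio - 1)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 slope_origin = unname(stats::coef(fit0)[1]),
                 slope_se = sm$coefficients["ratio", "Std. Error"],
                 n = length(y), degenerate = FALSE),
            class = "linear_ratio_fit")
}

#' @export
print.linear_ratio_fit <- function(x, ...) {
  cat(sprintf("Ratio-response fit (n = %d conditions):\n", x$n))
  cat(sprintf("  output = %.6g * (Y/X) + %.6g,  R^2 = %.5f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  through-origin slope: %.6g\n", x$slope_origin))
  if (x$degenerate) cat("  [degenerate: zero output variance]\n")
  invisible(x)
}

#' Rescale a ratiometric slope to a new RBS strength
#'
#' The sensitivity `c` is proportional to the output RBS translation
#' initiation rate (TIR, itself proportional to `1/K6`), so a slope observed
#' at one TIR predicts the slope at another by pure proportionality.
#'
#' @param slope_ref observed slope at the reference RBS.
#' @param TIR_ref,TIR_new TIR scores of the reference and new RBS.
#' @return `slope_ref * TIR_new / TIR_ref`.
#' @examples
#' tir_scaled_slope(220428, 8875, 4575)
#' @export
tir_scaled_slope <- function(slope_ref, TIR_ref, TIR_new) {
  check_scalar_num(slope_ref, "slope_ref", positive = TRUE)
  check_scalar_num(TIR_ref, "TIR_ref", positive = TRUE)
  check_scalar_num(TIR_new, "TIR_new", positive = TRUE)
  slope_ref * TIR_new / TIR_ref
}

#' Relative percent error between nominal and perturbed outputs
#'
#' The robustness metric `|nominal - perturbed| / nominal * 100` (%),
#' invariant under common rescaling of both arguments.
#'
#' @param nominal output under nominal conditions (> 0).
#' @param perturbed output under the perturbation.
#' @return Percentage error.
#' @examples
#' relative_percent_error(100, 95)
#' @export
relative_percent_error <- function(nominal, perturbed) {
  abort_if(any(!is.finite(nominal)) || any(nominal <= 0),
           "'nominal' must be strictly positive")
  abort_if(any(!is.finite(perturbed)) || any(perturbed < 0),
           "'perturbed' must be non-negative")
  abs(nominal - perturbed) / nominal * 100
}

#' Output spread over input pairs sharing one ratio
#'
#' A ratiometric circuit must give the same output for every `(X, Y)` pair
#' with the same `Y/X`; a resource-coupled but non-merging circuit does not.
#' This evaluates the model over such pairs and reports the spread.
#'
#' @param model function of `(X, Y)` returning the steady-state output.
#' @param pairs a list of [inducer_pair()]s, or a data.frame with columns
#'   `X` and `Y`; all pairs must share the same ratio to within `1e-9`
#'   (relative).
#' @return An object of class `spread_report`: `outputs`, `mean`,
#'   `max_rel_dev` (maximum relative deviation from the mean), `ratio`.
#' @export
constant_ratio_test <- function(model, pairs) {
  if (is.data.frame(pairs)) {
    X <- pairs$X; Y <- pairs$Y
  } else {
    X <- vapply(pairs, `[[`, numeric(1), "X")
    Y <- vapply(pairs, `[[`, numeric(1), "Y")
  }
  abort_if(any(X <= 0), "all pairs need X > 0")
  ratios <- Y / X
  abort_if(diff(range(ratios)) > 1e-9 * max(abs(ratios), 1),
           "pairs do not share a common ratio")
  outs <- vapply(seq_along(X), function(i) as.numeric(model(X[i], Y[i])),
                 numeric(1))
  m <- mean(outs)
  dev <- if (m == 0) 0 else max(abs(outs - m)) / abs(m)
  structure(list(outputs = outs, mean = m, max_rel_dev = dev,
                 ratio = ratios[1], X = X, Y = Y),
            class = "spread_report")
}

#' @export
print.spread_report <- function(x, ...) {
  cat(sprintf("Constant-ratio test at Y/X = %g over %d pairs:\n",
              x$ratio, length(x$outputs)))
  cat("  outputs:", paste(signif(x$outputs, 6), collapse = ", "), "\n")
  cat(sprintf("  mean %.6g, max relative deviation %.4g\n", x$mean,
              x$max_rel_dev))
  invisible(x)
}

#' Fold-change heat map under a context switch
#'
#' Evaluates `model(X, Y, ctx)` under two resource contexts (typically
#' competitor ON at 40 nM aTc versus OFF) over a grid, and reports the
#' unsigned fold change `max(on, off)/min(on, off)` at each point (>= 1 by
#' construction).  Points with zero or failed output are `NA`.
#'
#' @param model function of `(X, Y, ctx)` returning the steady-state output.
#' @param X_grid,Y_grid inducer grids (uM).
#' @param ctx_on,ctx_off the two [resource_context()]s to compare.
#' @return A matrix (rows = `X_grid`, columns = `Y_grid`) with attribute
#'   `max_fold` (the matrix maximum, NA-removed).
#' @export
fold_change_map <- function(model, X_grid, Y_grid, ctx_on, ctx_off) {
  abort_if(length(X_grid) == 0 || length(Y_grid) == 0,
           "grids must be non-empty")
  eval_ctx <- function(ctx) {
    outer(X_grid, Y_grid, Vectorize(function(x, y) {
      tryCatch(as.numeric(model(x, y, ctx)), error = function(e) NA_real_)
    }))
  }
  on <- eval_ctx(ctx_on)
  off <- eval_ctx(ctx_off)
  fc <- pmax(on, off) / pmin(on, off)
  fc[!is.finite(fc)] <- NA_real_   # zero or failed outputs are undefined
  dimnames(fc) <- list(X_uM = X_grid, Y_uM = Y_grid)
  attr(fc, "max_fold") <- if (all(is.na(fc))) NA_real_ else max(fc, na.rm = TRUE)
  fc
}

#' Resource-robustness report at one operating point
#'
#' Solves the full model at nominal resources and with the free pool scaled
#' by `fraction` (via [perturb_resource()] semantics on the context), and
#' reports the relative percent error of the output -- the robustness metric
#' of the incoherent merger analysis.
#'
#' @param p a [full_circuit_params()].
#' @param u an [inducer_pair()]; the default probes the low edge of the
#'   IPTG range at ratio 0.4.
#' @param fraction perturbed fraction of the nominal pool, in (0, 1].
#' @param ctx nominal [resource_context()].
#' @param ... passed to [full_steady_output()].
#' @return A list `(nominal, perturbed, rel_pct_error, fraction)`.
#' @export
resource_robustness <- function(p, u = inducer_pair(50, 20), fraction = 0.5,
                                ctx = default_context(p), ...) {
  stopifnot(inherits(ctx, "resource_context"))
  fraction <- perturb_resource(1, fraction)  # validates (0, 1]
  ctx_pert <- ctx
  ctx_pert$perturbation_fraction <- ctx$perturbation_fraction * fraction
  nominal <- full_steady_output(p, u, ctx, ...)
  perturbed <- full_steady_output(p, u, ctx_pert, ...)
  list(nominal = nominal, perturbed = perturbed,
       rel_pct_error = relative_percent_error(nominal, perturbed),
       fraction = fraction)
}
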