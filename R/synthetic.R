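#' Noise specification for synthetic datasets
#'
#' Measurement noise is multiplicative lognormal throughout: plate-reader
#' GFP/OD readouts and per-cell fluorescence are strictly positive with
#' large coefficients of variation (per-cell CV ~ 0.5 in the reference
#' flow-cytometry data), for which a lognormal is the standard convention.
#' A lognormal with target mean `m` and coefficient of variation `v` is
#' parameterized by moment matching: `sdlog = sqrt(log(1 + v^2))`,
#' `meanlog = log(m) - sdlog^2 / 2`.
#'
#' @param replicate_cv CV of plate-level multiplicative noise across
#'   biological replicates.
#' @param cell_cv CV of the per-cell fluorescence distribution.
#' @param n_replicates biological replicates per condition (the reference
#'   experiments used 3).
#' @param n_cells cells per flow-cytometry distribution.
#' @param seed mandatory RNG seed; generators have no implicit randomness.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(replicate_cv = 0.1, cell_cv = 0.5, n_replicates = 3L,
                       n_cells = 10000L, seed) {
  abort_if(missing(seed), "a seed is mandatory")
  check_scalar_num(replicate_cv, "replicate_cv", nonneg = TRUE)
  check_scalar_num(cell_cv, "cell_cv", nonneg = TRUE)
  check_scalar_num(n_replicates, "n_replicates", positive = TRUE)
  check_scalar_num(n_cells, "n_cells", positive = TRUE)
  check_scalar_num(seed, "seed")
  structure(list(replicate_cv = replicate_cv, cell_cv = cell_cv,
                 n_replicates = as.integer(n_replicates),
                 n_cells = as.integer(n_cells), seed = as.integer(seed)),
            class = "noise_spec")
}

lognormal_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic plate-reader dataset
#'
#' Emulates steady-state GFP/OD measurements over an inducer grid:
#' for each grid point the model's steady state is multiplied by
#' independent lognormal factors of mean 1 and CV `replicate_cv`, one per
#' biological replicate.  With `replicate_cv = 0` the outputs equal the
#' noiseless model exactly.  Runs are byte-reproducible under the noise
#' specification's seed and leave the caller's RNG state untouched.
#'
#' @param model function of `(X, Y)` returning the noiseless steady-state
#'   output; failures at a grid point flag its rows `NA`.
#' @param X_grid,Y_grid inducer grids (uM).
#' @param ns a [noise_spec()].
#' @param metadata extra metadata stored on the table.
#' @return A [dose_response_table()] with `n_replicates` rows per grid point
#'   and the noise spec recorded in its metadata.
#' @export
generate_plate_dataset <- function(model, X_grid, Y_grid, ns,
                                   metadata = list()) {
  stopifnot(inherits(ns, "noise_spec"))
  abort_if(length(X_grid) == 0 || length(Y_grid) == 0,
           "grids must be non-empty")
  pts <- expand.grid(X_uM = X_grid, Y_uM = Y_grid)
  base <- vapply(seq_len(nrow(pts)), function(i) {
    tryCatch(as.numeric(model(pts$X_uM[i], pts$Y_uM[i])),
             error = function(e) NA_real_)
  }, numeric(1))
  nrep <- ns$n_replicates
  outputs <- with_seed(ns$seed, {
    if (ns$replicate_cv > 0) {
      lp <- lognormal_pars(1, ns$replicate_cv)
      noise <- stats::rlnorm(nrow(pts) * nrep, lp$meanlog, lp$sdlog)
    } else {
      noise <- rep(1, nrow(pts) * nrep)
    }
    rep(base, each = nrep) * noise
  })
  dose_response_table(rep(pts$X_uM, each = nrep), rep(pts$Y_uM, each = nrep),
                      rep(seq_len(nrep), nrow(pts)), outputs,
                      metadata = c(metadata,
                                   list(kind = "synthetic_plate",
                                        noise = unclass(ns))))
}

#' Generate a synthetic per-cell fluorescence distribution
#'
#' Emulates a flow-cytometry readout: `n_cells` lognormal draws with the
#' requested mean and per-cell CV (moment-matched; see [noise_spec()]).
#' With `cell_cv = 0` all values equal the mean.
#'
#' @param mean target mean fluorescence (> 0).
#' @param ns a [noise_spec()]; `cell_cv`, `n_cells` and `seed` are used.
#' @return Numeric vector of `n_cells` strictly positive values.
#' @export
generate_flow_distribution <- function(mean, ns) {
  stopifnot(inherits(ns, "noise_spec"))
  check_scalar_num(mean, "mean", positive = TRUE)
  if (ns$cell_cv == 0) return(rep(mean, ns$n_cells))
  lp <- lognormal_pars(mean, ns$cell_cv)
  with_seed(ns$seed, stats::rlnorm(ns$n_cells, lp$meanlog, lp$sdlog))
}
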