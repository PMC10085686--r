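#' Transcriptional sensor parameters
#'
#' Describes one inducible transcription unit: a regulator (repressor or
#' activator) at fixed total concentration, an inducer that binds it, and a
#' target promoter present at a given copy-number concentration.  Both
#' binding steps (inducer-regulator and regulator-DNA) are treated at
#' thermodynamic equilibrium with single-site stoichiometry; Hill
#' coefficients default to 1 and are configurable.
#'
#' In `"repressor"` mode the inducer is *negative*: it binds the repressor
#' and prevents DNA binding, so activity increases with inducer
#' (de-repression; the IPTG/LacI arm).  In `"activator"` mode the inducer is
#' *positive*: the inducer-bound regulator activates transcription (the
#' salicylate/NahR arm).
#'
#' @param regulator_total total regulator concentration (uM).
#' @param inducer_Kd inducer-regulator dissociation constant (uM).
#' @param dna_Kd regulator-DNA dissociation constant (uM).
#' @param dna_copies target promoter concentration (uM).
#' @param max_rate maximal transcription rate per promoter copy (1/hr), so
#'   that activity is in uM/hr.
#' @param mode `"repressor"` (negative inducer) or `"activator"` (positive
#'   inducer).
#' @param hill Hill coefficient applied to both binding equilibria.
#' @return An object of class `sensor_params`.
#' @export
sensor_params <- function(regulator_total, inducer_Kd, dna_Kd, dna_copies,
                          max_rate, mode = c("repressor", "activator"),
                          hill = 1) {
  mode <- match.arg(mode)
  check_scalar_num(regulator_total, "regulator_total", positive = TRUE)
  check_scalar_num(inducer_Kd, "inducer_Kd", positive = TRUE)
  check_scalar_num(dna_Kd, "dna_Kd", positive = TRUE)
  check_scalar_num(dna_copies, "dna_copies", nonneg = TRUE)  # 0 = cassette absent
  check_scalar_num(max_rate, "max_rate", positive = TRUE)
  check_scalar_num(hill, "hill", positive = TRUE)
  structure(list(regulator_total = regulator_total, inducer_Kd = inducer_Kd,
                 dna_Kd = dna_Kd, dna_copies = dna_copies,
                 max_rate = max_rate, mode = mode, hill = hill),
            class = "sensor_params")
}

#' Equilibrium transcription rate of a sensor
#'
#' Computes the promoter activity at a given inducer concentration from the
#' equilibrium regulator-inducer and regulator-DNA binding described in
#' [sensor_params()].  Activity is bounded by `max_rate * dna_copies`, is
#' non-decreasing in the inducer for both modes, and (activator mode, no
#' basal term) is exactly zero at zero inducer.
#'
#' @param s a [sensor_params()] object.
#' @param inducer inducer concentration(s), uM; vectorized.
#' @return Transcription rate(s) in uM/hr.
#' @export
sensor_activity <- function(s, inducer) {
  stopifnot(inherits(s, "sensor_params"))
  abort_if(any(inducer < 0), "inducer concentrations must be non-negative")
  h <- s$hill
  vmax <- s$max_rate * s$dna_copies
  if (s$mode == "repressor") {
    free_rep <- s$regulator_total / (1 + (inducer / s$inducer_Kd)^h)
    vmax / (1 + (free_rep / s$dna_Kd)^h)
  } else {
    frac_bound <- (inducer / s$inducer_Kd)^h / (1 + (inducer / s$inducer_Kd)^h)
    active <- s$regulator_total * frac_bound
    vmax * (active / s$dna_Kd)^h / (1 + (active / s$dna_Kd)^h)
  }
}

#' Widest interval on which a sensor responds affinely
#'
#' Scans all contiguous sub-intervals of the supplied concentration grid and
#' returns the widest one on which [sensor_activity()] deviates from its
#' best affine fit by at most `tolerance`, measured relative to the span of
#' the fitted values.  This operationalizes the production-linearity design
#' requirement (A0): the circuit computes a clean ratio only inside each
#' sensor's linear range.
#'
#' @param s a [sensor_params()] object, or a plain function mapping
#'   concentration to activity (useful for composite production rates).
#' @param grid sorted concentration grid, at least 5 points (uM).
#' @param tolerance maximum allowed relative deviation from the affine fit.
#' @return An object of class `linear_range`: `low`, `high` (NA when no
#'   window of at least 3 points qualifies), `n_points`, `deviation`, and
#'   `tolerance`.  Deterministic; ties are broken towards more points, then
#'   towards the lower end of the grid.
#' @export
linear_range <- function(s, grid, tolerance) {
  f <- if (inherits(s, "sensor_params")) function(x) sensor_activity(s, x)
       else s
  abort_if(!is.numeric(grid) || length(grid) < 5L || is.unsorted(grid, strictly = TRUE),
           "'grid' must be a strictly increasing numeric vector of >= 5 points")
  check_scalar_num(tolerance, "tolerance", nonneg = TRUE)
  act <- vapply(grid, f, numeric(1))
  n <- length(grid)
  best <- NULL
  # only windows of >= 3 points are informative (2 points always fit a line)
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      x <- grid[i:j]; y <- act[i:j]
      fit <- stats::lm.fit(cbind(1, x), y)
      span <- diff(range(fit$fitted.values))
      if (span <= 0) {
        dev <- if (max(abs(fit$residuals)) == 0) 0 else Inf
      } else {
        dev <- max(abs(fit$residuals)) / span
      }
      if (dev <= tolerance) {
        width <- grid[j] - grid[i]
        if (is.null(best) || width > best$width ||
            (width == best$width && (j - i + 1L) > best$n)) {
          best <- list(i = i, j = j, width = width, n = j - i + 1L, dev = dev)
        }
      }
    }
  }
  if (is.null(best)) {
    out <- list(low = NA_real_, high = NA_real_, n_points = 0L,
                deviation = NA_real_, tolerance = tolerance)
  } else {
    out <- list(low = grid[best$i], high = grid[best$j], n_points = best$n,
                deviation = best$dev, tolerance = tolerance)
  }
  structure(out, class = "linear_range")
}

#' @export
print.linear_range <- function(x, ...) {
  if (is.na(x$low)) {
    cat(sprintf("No linear range at tolerance %g\n", x$tolerance))
  } else {
    cat(sprintf("Linear range [%g, %g] (%d grid points, max relative deviation %.3g, tolerance %g)\n",
                x$low, x$high, x$n_points, x$deviation, x$tolerance))
  }
  invisible(x)
}

#' Shared-resource context
#'
#' Describes the cell's pool of translational resource (ribosomes) and an
#' optional inducible competitor cassette (an aTc-driven RFP gene in the
#' reference circuit) that sequesters part of the pool.  Competitor demand
#' is a saturating function of the aTc level,
#' `demand(aTc) = comp_dmax * aTc / (comp_theta + aTc)` (dimensionless, in
#' units of mRNA/K ribosome-demand).
#'
#' @param R_tot total resource pool (uM).
#' @param comp_dmax maximal competitor ribosome demand (dimensionless).
#' @param comp_theta aTc level of half-maximal competitor demand (nM).
#' @param perturbation_fraction multiplicative factor applied to the free
#'   pool in robustness studies; in (0, 1].
#' @param aTc current competitor inducer level (nM); the default used by
#'   [free_resource()] and the full model when no explicit level is passed.
#' @return An object of class `resource_context`.
#' @export
resource_context <- function(R_tot, comp_dmax = 0, comp_theta = 10,
                             perturbation_fraction = 1, aTc = 0) {
  check_scalar_num(R_tot, "R_tot", positive = TRUE)
  check_scalar_num(comp_dmax, "comp_dmax", nonneg = TRUE)
  check_scalar_num(comp_theta, "comp_theta", positive = TRUE)
  check_scalar_num(perturbation_fraction, "perturbation_fraction")
  abort_if(perturbation_fraction <= 0 || perturbation_fraction > 1,
           "'perturbation_fraction' must lie in (0, 1]")
  check_scalar_num(aTc, "aTc", nonneg = TRUE)
  structure(list(R_tot = R_tot, comp_dmax = comp_dmax,
                 comp_theta = comp_theta,
                 perturbation_fraction = perturbation_fraction,
                 aTc = aTc),
            class = "resource_context")
}

competitor_demand <- function(ctx, aTc) {
  abort_if(any(aTc < 0), "aTc must be non-negative")
  ctx$comp_dmax * aTc / (ctx$comp_theta + aTc)
}

#' Free resource under competition
#'
#' Partitions the total resource pool among the circuit's mRNAs and the
#' competitor by the conservation relation
#' `R_free * (1 + sum(demands) + demand_comp(aTc)) = R_tot * fraction`,
#' the standard quasi-equilibrium form for ribosome competition.  Each
#' demand is a dimensionless mRNA/K ratio; the amount of resource allocated
#' to demand `d_i` is `d_i * R_free`, so free plus allocated always equals
#' the (possibly perturbed) total.
#'
#' @param ctx a [resource_context()].
#' @param circuit_demands numeric vector of dimensionless circuit demands
#'   (may be empty).
#' @param aTc competitor inducer level (nM).
#' @return Free resource level (uM), with attribute `allocations` (uM per
#'   demand, competitor last when present).
#' @export
free_resource <- function(ctx, circuit_demands = numeric(), aTc = ctx$aTc) {
  stopifnot(inherits(ctx, "resource_context"))
  abort_if(any(!is.finite(circuit_demands)) || any(circuit_demands < 0),
           "demands must be finite and non-negative")
  dc <- competitor_demand(ctx, aTc)
  total_demand <- sum(circuit_demands) + dc
  R_free <- ctx$perturbation_fraction * ctx$R_tot / (1 + total_demand)
  allocs <- circuit_demands * R_free
  if (dc > 0) allocs <- c(allocs, comp = dc * R_free)
  attr(R_free, "allocations") <- allocs
  R_free
}

#' Apply a multiplicative resource perturbation
#'
#' @param R resource level (uM).
#' @param fraction factor in (0, 1]; `0.5` is the perturbation magnitude
#'   used throughout the robustness analyses.
#' @return `R * fraction`.
#' @examples
#' perturb_resource(10, 0.5)
#' @export
perturb_resource <- function(R, fraction) {
  abort_if(any(R < 0), "'R' must be non-negative")
  check_scalar_num(fraction, "fraction")
  abort_if(fraction <= 0 || fraction > 1, "'fraction' must lie in (0, 1]")
  R * fraction
}
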