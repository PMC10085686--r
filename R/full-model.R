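#' Parameters of the full merger circuit model
#'
#' The full model tracks, for a given pair of inducer levels, the two
#' cassette mRNAs (`m_X` for the protease, `m_Y` for the output), the
#' protease `P_X`, the output `P_Y`, and the protease-target complex `C`.
#' Transcription rates come from the equilibrium sensor stage
#' ([sensor_activity()]); translation draws on a conserved ribosome pool
#' shared by both mRNAs, a constant background demand (host genes and the
#' chromosomal regulators, whose mRNAs are ribosome-saturated), and an
#' optional inducible competitor cassette.  The free pool is partitioned by
#' the quasi-equilibrium conservation relation (see [free_resource()]), so
#' free plus allocated ribosomes always equals the total.
#'
#' The ribosome-mRNA constants follow the Michaelis pattern
#' `K5 = (b5 + k5 + gamma)/a5` (protease mRNA) and
#' `K6 = (b6 + k6 + gamma)/a6` (output mRNA); the output RBS strength as a
#' translation initiation rate (TIR) score is proportional to `1/K6`, so
#' rescaling `1/K6` by a factor rescales the circuit's predicted ratiometric
#' sensitivity by the same factor.
#'
#' @param sensor_X [sensor_params()] of the protease arm (repressor mode;
#'   negative inducer X).
#' @param sensor_Y [sensor_params()] of the output arm (activator mode;
#'   positive inducer Y).
#' @param delta_X,delta_Y mRNA decay rate constants (1/hr).
#' @param a5,b5,k5 ribosome association (1/(uM*hr)), dissociation (1/hr) and
#'   translation (1/hr) rate constants of the protease mRNA.
#' @param a6,b6,k6 the same for the output mRNA; `1/K6` is the TIR knob.
#' @param R_tot total ribosome pool (uM).
#' @param d0 constant background ribosome demand (dimensionless).
#' @param a,b,k protease action rate constants, as in [merger_params()].
#' @param gamma dilution rate constant (1/hr), shared by all species.
#' @param protease_tag `TRUE` for the intact merger circuit; `FALSE` for the
#'   broken-merging control in which the output lacks the degradation tag
#'   and the protease cannot bind it.
#' @param gfp_per_uM calibration factor from output concentration (uM) to
#'   GFP/OD readout units.
#' @return An object of class `full_circuit_params` with derived `K5`, `K6`.
#' @seealso [full_rhs()], [full_steady_state()], [default_full_params()]
#' @export
full_circuit_params <- function(sensor_X, sensor_Y, delta_X, delta_Y,
                                a5, b5, k5, a6, b6, k6,
                                R_tot, d0, a, b, k, gamma,
                                protease_tag = TRUE, gfp_per_uM = 1) {
  stopifnot(inherits(sensor_X, "sensor_params"),
            inherits(sensor_Y, "sensor_params"))
  abort_if(sensor_X$mode != "repressor",
           "sensor_X must be a repressor-mode (negative inducer) sensor")
  abort_if(sensor_Y$mode != "activator",
           "sensor_Y must be an activator-mode (positive inducer) sensor")
  for (nm in c("delta_X", "delta_Y", "a5", "k5", "a6", "k6",
               "R_tot", "a", "b", "k", "gamma", "gfp_per_uM"))
    check_scalar_num(get(nm), nm, positive = TRUE)
  for (nm in c("b5", "b6", "d0")) check_scalar_num(get(nm), nm, nonneg = TRUE)
  K5 <- michaelis_constant(a5, b5, k5, gamma)
  K6 <- michaelis_constant(a6, b6, k6, gamma)
  structure(list(sensor_X = sensor_X, sensor_Y = sensor_Y,
                 delta_X = delta_X, delta_Y = delta_Y,
                 a5 = a5, b5 = b5, k5 = k5, K5 = K5,
                 a6 = a6, b6 = b6, k6 = k6, K6 = K6,
                 R_tot = R_tot, d0 = d0,
                 a = a, b = b, k = k, gamma = gamma,
                 protease_tag = isTRUE(protease_tag),
                 gfp_per_uM = gfp_per_uM),
            class = "full_circuit_params")
}

#' @export
print.full_circuit_params <- function(x, ...) {
  cat(sprintf("Full merger circuit (%s), gamma = %g/hr\n",
              if (x$protease_tag) "degradation tag intact"
              else "broken merging (no tag)", x$gamma))
  cat(sprintf("  translation: K5 = %g uM, K6 = %g uM (TIR ~ 1/K6), k5 = %g, k6 = %g\n",
              x$K5, x$K6, x$k5, x$k6))
  cat(sprintf("  protease:    a = %g, b = %g, k = %g (K = %g uM)\n",
              x$a, x$b, x$k, (x$b + x$k + x$gamma) / x$a))
  cat(sprintf("  resources:   R_tot = %g uM, background demand d0 = %g\n",
              x$R_tot, x$d0))
  invisible(x)
}

full_state_names <- c("m_X", "m_Y", "P_X", "P_Y", "C")

# default context: the circuit's own pool, no competitor, no perturbation
default_context <- function(p) resource_context(R_tot = p$R_tot)

#' Ribosome bookkeeping for a full-model state
#'
#' @param state full-model state vector (see [full_rhs()]).
#' @param p a [full_circuit_params()].
#' @param ctx a [resource_context()]; defaults to the circuit's own pool.
#' @return Free ribosome level (uM) with attribute `allocations` (background,
#'   m_X, m_Y, competitor); free + sum(allocations) equals the perturbed
#'   total pool exactly.
#' @export
free_ribosomes <- function(state, p, ctx = default_context(p)) {
  free_resource(ctx, c(background = p$d0,
                       m_X = state[[1]] / p$K5,
                       m_Y = state[[2]] / p$K6))
}

#' Right-hand side of the full circuit ODE model
#'
#' State order is `m_X, m_Y, P_X, P_Y, C` (uM).  Transcription follows the
#' equilibrium sensor stage; translation rates are `k5 * (m_X/K5) * R` and
#' `k6 * (m_Y/K6) * R` with `R` the free ribosome level from the shared-pool
#' conservation relation; the protein stage is the mass-action merger core
#' (or its broken-merging variant when the degradation tag is absent); all
#' species dilute at `gamma`.  In the sensors' linear ranges and at mRNA
#' quasi-steady state this reduces to [merger_rhs()] with effective
#' production constants (see [full_reduced_constants()]).
#'
#' @param state named or unnamed numeric vector of the five species, all
#'   non-negative.
#' @param p a [full_circuit_params()].
#' @param u an [inducer_pair()].
#' @param ctx a [resource_context()]; its `aTc` and `perturbation_fraction`
#'   fields set the competitor level and resource perturbation.
#' @return Named vector of time derivatives (uM/hr).
#' @export
full_rhs <- function(state, p, u, ctx = default_context(p)) {
  stopifnot(inherits(p, "full_circuit_params"))
  abort_if(length(state) != 5L || any(!is.finite(state)),
           "state must be five finite concentrations (m_X, m_Y, P_X, P_Y, C)")
  abort_if(any(state < 0), "invalid state: negative concentrations")
  full_rhs_core(state, p,
                T_X = sensor_activity(p$sensor_X, u$X),
                T_Y = sensor_activity(p$sensor_Y, u$Y),
                R_top = ctx$perturbation_fraction * ctx$R_tot,
                dc = competitor_demand(ctx, ctx$aTc))
}

# shared math; the transcription rates and resource-context constants are
# fixed along a trajectory, so steady-state solving precomputes them
full_rhs_core <- function(state, p, T_X, T_Y, R_top, dc) {
  m_X <- state[[1]]; m_Y <- state[[2]]
  P_X <- state[[3]]; P_Y <- state[[4]]; C <- state[[5]]
  R <- R_top / (1 + p$d0 + dc + m_X / p$K5 + m_Y / p$K6)
  F_X <- p$k5 * (m_X / p$K5) * R
  F_Y <- p$k6 * (m_Y / p$K6) * R
  if (p$protease_tag) {
    bind <- p$a * P_X * P_Y
    dP_X <- F_X - bind + (p$b + p$k) * C - p$gamma * P_X
    dP_Y <- F_Y - bind + p$b * C - p$gamma * P_Y
    dC <- bind - (p$b + p$k + p$gamma) * C
  } else {
    dP_X <- F_X - p$gamma * P_X
    dP_Y <- F_Y - p$gamma * P_Y
    dC <- -p$gamma * C
  }
  c(m_X = T_X - p$delta_X * m_X,
    m_Y = T_Y - p$delta_Y * m_Y,
    P_X = dP_X, P_Y = dP_Y, C = dC)
}

#' Steady state of the full circuit model
#'
#' Convenience wrapper around [solve_steady_state()] for [full_rhs()].
#'
#' @inheritParams full_rhs
#' @param tol,t_max,check_unique passed to [solve_steady_state()]; `t_max`
#'   defaults to `200/gamma`.
#' @return A `steady_state_result` over the five species.
#' @export
full_steady_state <- function(p, u, ctx = default_context(p), tol = 1e-9,
                              t_max = 200 / p$gamma, check_unique = TRUE) {
  init <- stats::setNames(numeric(5), full_state_names)
  T_X <- sensor_activity(p$sensor_X, u$X)
  T_Y <- sensor_activity(p$sensor_Y, u$Y)
  R_top <- ctx$perturbation_fraction * ctx$R_tot
  dc <- competitor_demand(ctx, ctx$aTc)
  solve_steady_state(function(s) full_rhs_core(s, p, T_X, T_Y, R_top, dc),
                     init, tol = tol, t_max = t_max,
                     check_unique = check_unique)
}

#' Steady-state output readout of the full model
#'
#' @inheritParams full_steady_state
#' @param units `"gfp"` to apply the GFP/OD calibration factor, `"uM"` for
#'   raw concentration.
#' @param ... passed to [full_steady_state()].
#' @return The steady-state output level; errors if the solve does not
#'   converge.
#' @export
full_steady_output <- function(p, u, ctx = default_context(p),
                               units = c("gfp", "uM"), ...) {
  units <- match.arg(units)
  ss <- full_steady_state(p, u, ctx, ...)
  abort_if(!ss$converged, "full model did not reach steady state")
  out <- ss$state[["P_Y"]]
  if (units == "gfp") out <- out * p$gfp_per_uM
  out
}

#' Effective reduced-model constants of a full parameter set
#'
#' Linearizes the sensor stage at a reference operating point (secant slopes
#' through the origin) and propagates through the mRNA quasi-steady state to
#' the effective production constants of the merger core:
#' `k_X = k5 * T_X(X_ref) / (delta_X * K5 * X_ref)` and the analogue for
#' `k_Y`.  From these the ratiometric sensitivity
#' `c = gamma * k_Y * K / ((k + gamma) * k_X)` follows; note `k_Y` is
#' proportional to `1/K6`, which carries the TIR-proportional tuning of `c`.
#'
#' @param p a [full_circuit_params()].
#' @param X_ref,Y_ref reference inducer levels (uM) at which the sensor
#'   secants are taken; defaults are the mid-points of the declared linear
#'   ranges.
#' @param ctx a [resource_context()] used to evaluate the operating-point
#'   free pool and total protease.
#' @return A list with `k_X`, `k_Y`, `c` (uM output per unit ratio), `c_gfp`
#'   (GFP/OD per unit ratio), `R_free_ref`, and `merger` (a [merger_params()]
#'   with the operating-point `P_XT` at `X_ref`).
#' @export
full_reduced_constants <- function(p, X_ref = 150, Y_ref = 25,
                                   ctx = default_context(p)) {
  stopifnot(inherits(p, "full_circuit_params"))
  T_X <- sensor_activity(p$sensor_X, X_ref)
  T_Y <- sensor_activity(p$sensor_Y, Y_ref)
  k_X <- p$k5 * T_X / (p$delta_X * p$K5 * X_ref)
  k_Y <- p$k6 * T_Y / (p$delta_Y * p$K6 * Y_ref)
  m_X <- T_X / p$delta_X
  m_Y <- T_Y / p$delta_Y
  R_free <- as.numeric(free_resource(ctx, c(p$d0, m_X / p$K5, m_Y / p$K6)))
  P_XT <- k_X * X_ref * R_free / p$gamma
  mp <- merger_params(k_X = k_X, k_Y = k_Y, a = p$a, b = p$b, k = p$k,
                      gamma = p$gamma, P_XT = P_XT)
  c_uM <- sensitivity_constant(mp)
  list(k_X = k_X, k_Y = k_Y, c = c_uM, c_gfp = c_uM * p$gfp_per_uM,
       R_free_ref = R_free, merger = mp)
}

#' Effective broken-merging constants of a full parameter set
#'
#' Maps a full parameter set (with or without the degradation tag) onto the
#' saturating broken-merging law.  The per-inducer demand slopes are sensor
#' secants at the reference point, `c1 = T_X(X_ref) / (delta_X * K5 * X_ref)`
#' (and the analogue for `c2`), rescaled by the baseline loading
#' `1/(1 + d0 + demand_comp)` so that the law's denominator reproduces the
#' conservation relation; the amplitude keeps the raw (possibly perturbed)
#' pool `R_tot`.
#'
#' @inheritParams full_reduced_constants
#' @return A list `(k6, R_tot_eff, gamma, c1, c2)` ready for
#'   [broken_merging_output()].
#' @export
broken_reduced_constants <- function(p, X_ref = 150, Y_ref = 25,
                                     ctx = default_context(p)) {
  stopifnot(inherits(p, "full_circuit_params"))
  dc <- competitor_demand(ctx, ctx$aTc)
  base <- 1 + p$d0 + dc
  c1 <- sensor_activity(p$sensor_X, X_ref) / (p$delta_X * p$K5 * X_ref) / base
  c2 <- sensor_activity(p$sensor_Y, Y_ref) / (p$delta_Y * p$K6 * Y_ref) / base
  # with demands rescaled by the baseline loading, the amplitude keeps the
  # raw (possibly perturbed) pool: amplitude * c2 * Y then reproduces
  # k6 * (m_Y/K6) * R_free / gamma
  list(k6 = p$k6,
       R_tot_eff = ctx$perturbation_fraction * ctx$R_tot,
       gamma = p$gamma, c1 = c1, c2 = c2)
}
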