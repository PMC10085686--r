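#' Kinetic parameters of the core incoherent merger module
#'
#' Bundles the mass-action rate constants of the minimal merger circuit: two
#' resource-dependent production reactions (input X drives the protease P_X,
#' input Y drives the output P_Y), protease-target complex formation and
#' catalytic degradation, and first-order dilution of all species.
#'
#' @param k_X production rate constant of P_X per unit X per unit resource
#'   (1/(uM*hr)).
#' @param k_Y production rate constant of P_Y per unit Y per unit resource
#'   (1/(uM*hr)).
#' @param a protease-target association rate constant (1/(uM*hr)).
#' @param b complex dissociation rate constant (1/hr).
#' @param k catalytic degradation rate constant (1/hr).
#' @param gamma dilution rate constant (1/hr).
#' @param P_XT total protease concentration (P_X + complex) at the operating
#'   point (uM); used by the dilution-vs-degradation assumption check. May be
#'   `NA` if no operating point has been fixed yet.
#' @return An object of class `merger_params`: a named list of the rate
#'   constants plus the derived Michaelis constant `K = (b + k + gamma)/a`.
#' @seealso [sensitivity_constant()], [merger_rhs()], [check_assumptions()]
#' @examples
#' p <- merger_params(k_X = 0.01, k_Y = 0.03, a = 121, b = 10, k = 110,
#'                    gamma = 1, P_XT = 0.5)
#' p$K
#' @export
merger_params <- function(k_X, k_Y, a, b, k, gamma, P_XT = NA_real_) {
  check_scalar_num(k_X, "k_X", positive = TRUE)
  check_scalar_num(k_Y, "k_Y", positive = TRUE)
  check_scalar_num(a, "a", positive = TRUE)
  check_scalar_num(b, "b", positive = TRUE)
  check_scalar_num(k, "k", positive = TRUE)
  check_scalar_num(gamma, "gamma", positive = TRUE)
  if (!is.na(P_XT)) check_scalar_num(P_XT, "P_XT", positive = TRUE)
  K <- michaelis_constant(a, b, k, gamma)
  structure(list(k_X = k_X, k_Y = k_Y, a = a, b = b, k = k, gamma = gamma,
                 K = K, P_XT = P_XT),
            class = "merger_params")
}

#' @export
print.merger_params <- function(x, ...) {
  cat("Merger module parameters (uM, hr):\n")
  cat(sprintf("  production  k_X = %g, k_Y = %g\n", x$k_X, x$k_Y))
  cat(sprintf("  protease    a = %g, b = %g, k = %g  (K = %g uM)\n",
              x$a, x$b, x$k, x$K))
  cat(sprintf("  dilution    gamma = %g\n", x$gamma))
  if (!is.na(x$P_XT)) cat(sprintf("  operating total protease P_XT = %g uM\n",
                                  x$P_XT))
  invisible(x)
}

#' A pair of inducer concentrations
#'
#' @param X concentration of the first input (the protease-driving, negative
#'   inducer; IPTG in the reference implementation), in uM.
#' @param Y concentration of the second input (the output-driving, positive
#'   inducer; salicylate), in uM.
#' @return An object of class `inducer_pair`.
#' @examples
#' inducer_pair(100, 40)
#' @export
inducer_pair <- function(X, Y) {
  check_scalar_num(X, "X", nonneg = TRUE)
  check_scalar_num(Y, "Y", nonneg = TRUE)
  structure(list(X = X, Y = Y), class = "inducer_pair")
}

#' @export
print.inducer_pair <- function(x, ...) {
  cat(sprintf("Inducer pair: X = %g uM, Y = %g uM\n", x$X, x$Y))
  invisible(x)
}

#' Michaelis constant of an enzymatic step with dilution
#'
#' For a binding/catalysis scheme with association rate `a`, dissociation
#' rate `b`, catalytic rate `k` and dilution `gamma`, the effective
#' Michaelis constant is `K = (b + k + gamma)/a`.  The same pattern defines
#' the ribosome-mRNA constants K5 and K6 of the full circuit model, whose
#' reciprocal 1/K6 is proportional to the translation initiation rate (TIR)
#' of the output gene.
#'
#' @param a association rate constant (1/(uM*hr)), strictly positive.
#' @param b dissociation rate constant (1/hr), non-negative.
#' @param k catalytic rate constant (1/hr), non-negative.
#' @param gamma dilution rate constant (1/hr), non-negative.
#' @return The Michaelis constant in uM.
#' @examples
#' michaelis_constant(a = 2, b = 1, k = 2, gamma = 1) # 2
#' @export
michaelis_constant <- function(a, b, k, gamma) {
  check_scalar_num(a, "a", positive = TRUE)
  check_scalar_num(b, "b", nonneg = TRUE)
  check_scalar_num(k, "k", nonneg = TRUE)
  check_scalar_num(gamma, "gamma", nonneg = TRUE)
  abort_if(b + k + gamma <= 0, "at least one of b, k, gamma must be positive")
  (b + k + gamma) / a
}

#' Sensitivity constant of the ratiometric law
#'
#' Under the module's operating assumptions (first-order protease regime and
#' degradation faster than dilution) the steady-state output obeys
#' `P_Y = c * Y / X` with slope
#' `c = gamma * k_Y * K / ((k + gamma) * k_X)`.
#' The slope is independent of the shared resource level and is proportional
#' to `k_Y` (and hence to the output RBS strength, i.e. to 1/K6 in the full
#' circuit), which is the circuit's tuning knob.
#'
#' @param p a [merger_params()] object.
#' @return The slope `c` (output concentration per unit input ratio).
#' @examples
#' p <- merger_params(k_X = 1, k_Y = 10, a = 10, b = 0.5, k = 9, gamma = 0.5)
#' sensitivity_constant(p)
#' @export
sensitivity_constant <- function(p) {
  stopifnot(inherits(p, "merger_params"))
  p$gamma * p$k_Y * p$K / ((p$k + p$gamma) * p$k_X)
}

#' Reduced-model steady-state output of the merger circuit
#'
#' Evaluates the closed-form ratiometric law `P_Y = c * (Y/X)`.  The value is
#' exactly invariant under common scaling of the two inputs and has zero
#' sensitivity to the shared resource pool.
#'
#' @param c sensitivity constant (slope), strictly positive.
#' @param u an [inducer_pair()], or a list/data.frame with numeric fields
#'   `X` and `Y` (vectors allowed, recycled in the usual way).
#' @return Steady-state output, same units as `c` per unit ratio.
#' @examples
#' reduced_merger_output(220428, inducer_pair(X = 100, Y = 40))
#' @export
reduced_merger_output <- function(c, u) {
  abort_if(!is.numeric(c) || any(c <= 0), "'c' must be strictly positive")
  X <- u$X
  Y <- u$Y
  abort_if(any(!is.finite(X)) || any(!is.finite(Y)) || any(Y < 0),
           "inducer concentrations must be finite and non-negative")
  abort_if(any(X <= 0), "ratio undefined: X must be strictly positive")
  c * Y / X
}

#' Right-hand side of the minimal merger ODE model
#'
#' Mass-action dynamics of the three-species core: protease `P_X`, output
#' `P_Y` and protease-target complex `C`, with resource-dependent production,
#' complex formation/dissociation, catalytic degradation of the output, and
#' dilution of every species.
#'
#' @param state named numeric vector `c(P_X=, P_Y=, C=)`, all non-negative
#'   (uM).
#' @param p a [merger_params()] object.
#' @param u an [inducer_pair()].
#' @param R free resource level driving both production reactions (uM).
#' @return Named vector of time derivatives (uM/hr).
#' @examples
#' p <- merger_params(0.01, 0.03, 121, 10, 110, 1)
#' merger_rhs(c(P_X = 0, P_Y = 0, C = 0), p, inducer_pair(100, 20), R = 5)
#' @export
merger_rhs <- function(state, p, u, R) {
  stopifnot(inherits(p, "merger_params"))
  abort_if(length(state) != 3L || any(!is.finite(state)),
           "state must be three finite concentrations (P_X, P_Y, C)")
  abort_if(any(state < 0), "invalid state: negative concentrations")
  check_scalar_num(R, "R", nonneg = TRUE)
  P_X <- state[[1]]; P_Y <- state[[2]]; C <- state[[3]]
  bind <- p$a * P_X * P_Y
  c(P_X = p$k_X * u$X * R - bind + (p$b + p$k) * C - p$gamma * P_X,
    P_Y = p$k_Y * u$Y * R - bind + p$b * C - p$gamma * P_Y,
    C   = bind - (p$b + p$k + p$gamma) * C)
}

#' Reduced steady-state law of the broken-merging control circuit
#'
#' When the degradation tag is removed from the output protein the protease
#' no longer degrades it, and the only coupling between the two arms is
#' sequestration of shared ribosomes.  The steady-state output then follows
#' the saturating law
#' `P_Y = (k6 * R_tot / gamma) * c2 * Y_T / (1 + c1 * X_T + c2 * Y_T)`,
#' which is not ratiometric (pairs with equal Y/X give different outputs)
#' and is directly proportional to the resource pool `R_tot`, so a resource
#' perturbation passes straight through to the output.
#'
#' @param k6 catalytic translation rate constant of the output mRNA (1/hr).
#' @param R_tot total resource (ribosome) pool (uM).
#' @param gamma dilution rate constant (1/hr).
#' @param c1 lumped sensor/ribosome-demand constant of the X (protease) arm
#'   (1/uM of X_T).
#' @param c2 lumped sensor/ribosome-demand constant of the Y (output) arm
#'   (1/uM of Y_T).
#' @param X_T concentration of the first inducer (uM); vectors allowed.
#' @param Y_T concentration of the second inducer (uM); vectors allowed.
#' @return Steady-state output concentration (uM); recycles `X_T`/`Y_T`.
#' @examples
#' broken_merging_output(10, 10, 1, c1 = 0.01, c2 = 0.1, X_T = 100, Y_T = 20)
#' @export
broken_merging_output <- function(k6, R_tot, gamma, c1, c2, X_T, Y_T) {
  check_scalar_num(k6, "k6", nonneg = TRUE)
  check_scalar_num(R_tot, "R_tot", nonneg = TRUE)
  check_scalar_num(gamma, "gamma", positive = TRUE)
  check_scalar_num(c1, "c1", nonneg = TRUE)
  check_scalar_num(c2, "c2", nonneg = TRUE)
  abort_if(any(X_T < 0) || any(Y_T < 0), "inducer totals must be non-negative")
  (k6 * R_tot / gamma) * c2 * Y_T / (1 + c1 * X_T + c2 * Y_T)
}

#' Check the operating assumptions of the ratiometric reduction
#'
#' The closed-form law `P_Y = c * Y/X` holds when
#' (A1) the protease works in its first-order regime, `P_Y << K`, and
#' (A2) dilution is negligible against protease degradation,
#' `gamma << P_XT * (k + gamma) / K`.
#' Both are operationalized as margin ratios that must not exceed
#' `strictness` (default 0.1).  The production-linearity assumption (A0)
#' belongs to the sensor stage and is assessed by [linear_range()]; it is
#' echoed here for completeness when a `linear_range` report is supplied.
#'
#' @param p a [merger_params()] object with `P_XT` set (the operating-point
#'   total protease); if `P_XT` is `NA` it is taken from the steady state as
#'   `P_X + C`.
#' @param ss a `steady_state_result` from [solve_steady_state()] whose state
#'   contains `P_Y` (and `P_X`, `C` when `P_XT` must be inferred).
#' @param strictness how small a ratio qualifies as "much less than";
#'   in (0, 1).
#' @param a0 optional `linear_range` report(s) to attach as the A0 record.
#' @return An object of class `assumption_report` with elements `A1`, `A2`
#'   (each `list(margin, pass)`), `strictness`, and optionally `A0`.
#' @export
check_assumptions <- function(p, ss, strictness = 0.1, a0 = NULL) {
  stopifnot(inherits(p, "merger_params"))
  abort_if(!inherits(ss, "steady_state_result"),
           "'ss' must be a steady_state_result")
  abort_if(!isTRUE(ss$converged), "steady state did not converge")
  check_scalar_num(strictness, "strictness", positive = TRUE)
  abort_if(strictness >= 1, "'strictness' must lie in (0, 1)")
  P_Y <- ss$state[["P_Y"]]
  P_XT <- p$P_XT
  if (is.na(P_XT)) {
    abort_if(!all(c("P_X", "C") %in% names(ss$state)),
             "P_XT not set and state lacks P_X/C to infer it")
    P_XT <- ss$state[["P_X"]] + ss$state[["C"]]
  }
  m1 <- P_Y / p$K
  m2 <- p$gamma * p$K / (P_XT * (p$k + p$gamma))
  rep <- structure(list(
    A1 = list(margin = m1, pass = m1 <= strictness),
    A2 = list(margin = m2, pass = m2 <= strictness),
    A0 = a0,
    strictness = strictness
  ), class = "assumption_report")
  rep
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("Assumption report (strictness %g):\n", x$strictness))
  cat(sprintf("  A1 (first-order protease, P_Y/K):            margin %.4g  [%s]\n",
              x$A1$margin, if (x$A1$pass) "pass" else "FAIL"))
  cat(sprintf("  A2 (degradation >> dilution, gK/(P_XT(k+g))): margin %.4g  [%s]\n",
              x$A2$margin, if (x$A2$pass) "pass" else "FAIL"))
  if (!is.null(x$A0)) cat("  A0 (sensor linearity): see attached linear_range report(s)\n")
  invisible(x)
}
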