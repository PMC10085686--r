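# Independent oracles, kept deliberately separate from the package's own
# solution paths: the protein-stage steady state is solved algebraically
# (quadratic in P_Y), and linear-range detection is re-derived by a direct
# window scan with lm().

# Algebraic steady state of the protease/output/complex stage given constant
# production fluxes F_X, F_Y.  From the stationarity conditions:
#   P_XT = F_X / gamma,  C = P_X * P_Y / K,  P_X = P_XT / (1 + P_Y/K),
#   F_Y = (k + gamma) * C + gamma * P_Y
# which reduce to the quadratic
#   (gamma/K) P_Y^2 + ((k+gamma) P_XT / K + gamma - F_Y/K) P_Y - F_Y = 0.
oracle_protein_steady <- function(F_X, F_Y, a, b, k, gamma) {
  K <- (b + k + gamma) / a
  P_XT <- F_X / gamma
  A <- gamma / K
  B <- (k + gamma) * P_XT / K + gamma - F_Y / K
  C0 <- -F_Y
  P_Y <- (-B + sqrt(B^2 - 4 * A * C0)) / (2 * A)
  P_X <- P_XT / (1 + P_Y / K)
  c(P_X = P_X, P_Y = P_Y, C = P_X * P_Y / K)
}

# Same, for the minimal merger model with explicit resource level R.
oracle_merger_steady <- function(p, u, R) {
  oracle_protein_steady(p$k_X * u$X * R, p$k_Y * u$Y * R,
                        p$a, p$b, p$k, p$gamma)
}

# Full-model steady state: mRNAs settle independently of the proteins, the
# free pool follows from conservation, then the protein stage is algebraic.
oracle_full_steady <- function(p, u, ctx = default_resource_context()) {
  m_X <- sensor_activity(p$sensor_X, u$X) / p$delta_X
  m_Y <- sensor_activity(p$sensor_Y, u$Y) / p$delta_Y
  dc <- p_comp_demand(ctx)
  R <- ctx$perturbation_fraction * ctx$R_tot /
    (1 + p$d0 + dc + m_X / p$K5 + m_Y / p$K6)
  F_X <- p$k5 * (m_X / p$K5) * R
  F_Y <- p$k6 * (m_Y / p$K6) * R
  if (p$protease_tag) {
    prot <- oracle_protein_steady(F_X, F_Y, p$a, p$b, p$k, p$gamma)
  } else {
    prot <- c(P_X = F_X / p$gamma, P_Y = F_Y / p$gamma, C = 0)
  }
  c(m_X = m_X, m_Y = m_Y, prot)
}

p_comp_demand <- function(ctx) ctx$comp_dmax * ctx$aTc / (ctx$comp_theta + ctx$aTc)

# Brute-force widest affine window: re-derived with lm() over every
# contiguous window of >= 3 points.
oracle_linear_range <- function(f, grid, tolerance) {
  act <- vapply(grid, f, numeric(1))
  n <- length(grid)
  best <- NULL
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      d <- data.frame(x = grid[i:j], y = act[i:j])
      fit <- lm(y ~ x, data = d)
      span <- diff(range(fitted(fit)))
      dev <- if (span <= 0) {
        if (max(abs(resid(fit))) == 0) 0 else Inf
      } else max(abs(resid(fit))) / span
      if (dev <= tolerance) {
        width <- grid[j] - grid[i]
        if (is.null(best) || width > best$width ||
            (width == best$width && (j - i + 1L) > best$n))
          best <- list(low = grid[i], high = grid[j], width = width,
                       n = j - i + 1L)
      }
    }
  }
  best
}
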