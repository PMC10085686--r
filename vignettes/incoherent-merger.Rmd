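---
title: "Modelling ratiometric gene expression with the incoherent merger network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ratiometric gene expression with the incoherent merger network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mergenet)
```

## The circuit and its model

A ratiometric response makes an output protein's steady-state level track
the *ratio* of two input signals rather than either signal alone.  The
incoherent merger network achieves this at the gene-expression layer: one
inducer (Y, salicylate acting through the NahR activator) drives production
of the output protein P_Y, while the other (X, IPTG acting through LacI
de-repression) drives a protease P_X that degrades P_Y through a degradation
tag.  Both production reactions draw on the same translational resource pool
R (ribosomes), which closes an incoherent feedforward loop: more R means
more output *and* more of the output's degrader.

The minimal model keeps three species under mass action,

$$\dot P_X = k_X X R - a P_X P_Y + (b + k) C - \gamma P_X,$$
$$\dot P_Y = k_Y Y R - a P_X P_Y + b C - \gamma P_Y,$$
$$\dot C = a P_X P_Y - (b + k + \gamma) C,$$

with dilution rate $\gamma$ and protease Michaelis constant
$K = (b + k + \gamma)/a$.  Under two operating assumptions the steady state
collapses to the ratiometric law

$$P_Y^\ast = c \,\frac{Y}{X}, \qquad
  c = \frac{\gamma\, k_Y K}{(k + \gamma)\, k_X},$$

which contains no $R$: the resource dependence cancels exactly.  The
assumptions, checked by `check_assumptions()`, are

* **A1 (first-order protease regime)** $P_Y \ll K$, margin $P_Y/K$;
* **A2 (degradation beats dilution)** $\gamma \ll P_{XT}(k+\gamma)/K$,
  margin $\gamma K / (P_{XT}(k+\gamma))$;

plus **A0**: production of P_X and P_Y must be linear in X, Y and R, which
belongs to the sensor stage and is assessed with `linear_range()`.  "Much
less than" is operationalized as a margin ratio of at most 0.1 (the
`strictness` argument); at that strictness the reduced and full models agree
to within about 5% (see below), which is what the approximation is for.

## The full model

`full_rhs()` tracks the two cassette mRNAs, the protease, the output and the
protease-output complex.  Transcription comes from equilibrium sensor
binding (`sensor_activity()`): inducer-regulator and regulator-DNA binding
are fast, single-site, with configurable Hill coefficients (default 1, since
no cooperativity information is printed).  Translation uses the standard
quasi-equilibrium resource-competition form: each mRNA exerts a
dimensionless ribosome demand $m_i/K_i$, the free pool follows the
conservation relation

$$R_{\mathrm{free}} = \frac{R_{\mathrm{tot}}}
  {1 + d_0 + d_{\mathrm{comp}}(\mathrm{aTc}) + m_X/K_5 + m_Y/K_6},$$

and production of protein $i$ is $k_i (m_i/K_i) R_{\mathrm{free}}$.  Here
$d_0$ is a constant background demand (host genes and the chromosomal
regulators, whose saturated mRNAs sequester a fixed share), and the
competitor term is a saturating function of the aTc level driving an RFP
cassette.  Free plus allocated ribosomes equal the total at every evaluation
by construction, which the tests assert to machine precision.

The ribosome-mRNA constants follow the same Michaelis pattern as the
protease, $K_6 = (b_6 + k_6 + \gamma)/a_6$; the RBS strength of the output
gene, scored as a translation initiation rate (TIR), is proportional to
$1/K_6$, and therefore so is the ratiometric sensitivity $c$.
`default_full_params(tir = )` exposes exactly this knob, and
`tir_scaled_slope()` is the corresponding pure proportionality on observed
slopes.

**Broken merging.**  Removing the degradation tag (`protease_tag = FALSE`)
decouples the protease from the output.  The steady state then follows the
saturating, non-ratiometric law

$$P_Y = \frac{k_6 R_{\mathrm{tot}}}{\gamma}
  \frac{c_2 Y_T}{1 + c_1 X_T + c_2 Y_T},$$

(`broken_merging_output()`), where $c_1, c_2$ are per-inducer mRNA-demand
slopes divided by the baseline loading (`broken_reduced_constants()`).  This
law is directly proportional to $R_{\mathrm{tot}}$: a halved pool passes
straight through as a 2-fold output change, the contrast that makes the
intact merger's ~5% attenuation meaningful.

## Default parameters: a synthetic set for a stated regime

What is publicly known about the reference circuit fixes its *regime* —
linear ranges, assumption margins, robustness magnitudes — rather than a
complete kinetic table.  `default_full_params()` is therefore a synthetic,
internally consistent set chosen once so that every one of those regime
statements holds, and not revisited:

| choice | value | why |
|---|---|---|
| dilution $\gamma$ | 1 /hr | growth conditions are specified but not a doubling time; 42 min doubling is a reasonable convention, and $\gamma$ is configurable |
| protease $a, b, k$ | 121 /(uM hr), 10 /hr, 110 /hr | $K = 1$ uM and catalysis two orders above dilution, consistent with a strong protease and the strongest degradation tag |
| sensor constants | see `default_full_params()` | both arms sit deep in their linear regimes over the declared ranges (IPTG 50-400 uM, Sal 0-50 uM); secant nonlinearity stays near ±1% |
| transcription/translation rates | lumped effective values | sized so the A2 margin is ≈0.045 at the low-IPTG edge and the A1 margin ≤0.02 across the grid — inside strictness 0.1, and yielding the ~5% residual sensitivity to a halved pool that the intact circuit shows |
| $R_{\mathrm{tot}} = 10$ uM, $d_0 = 1$ | | free pool ≈ 5 uM at the operating point |
| competitor demand | max 2.5, half-max at 10 nM aTc | full induction (40 nM) halves the free pool — the same 50% magnitude used in the perturbation analysis |
| `gfp_per_uM` | 12175718.8 | unit calibration only: makes the default TIR-8875 slope equal the observed 220428 GFP/OD per unit ratio |

Because the set is synthetic, green tests establish that the *implemented
model class* reproduces the reported regime statements (slope scaling with
TIR, ≤5% reduced/full agreement under A1/A2, ~5% robustness, ≤1.2-fold
versus 2-fold competitor response); they do not re-estimate the wet-lab
kinetics.

## Numerical choices

* **Steady states** (`solve_steady_state()`): adaptive Dormand-Prince RK45
  integration in growing time chunks, each followed by a damped-Newton
  polish on the right-hand side with a numeric Jacobian; the polished state
  is accepted only once its residual meets tolerance, so the root finder
  cannot commit to a spurious point far from equilibrium.  Convergence is
  measured as max |dy/dt| relative to the model's production scale (the RHS
  at the zero state), default tolerance 1e-9, horizon 200/γ.  States are
  projected onto the non-negative orthant (the models are positively
  invariant; projection only removes round-off undershoot).  By default each
  solve is repeated from a second initialization and the two states must
  agree within 10x tolerance — a guard against unnoticed multistability.
  Grid sweeps inside tests disable that doubling for speed; dedicated tests
  keep it on.
* **Fitting** (`fit_reduced_merger()`, `fit_broken_merging()`): bounded
  multistart nonlinear least squares on replicate means (10 log-uniform
  starts plus one central start, fixed seed), optimizing in log10 parameter
  space.  Confidence intervals are linearized but use the
  heteroskedasticity-consistent sandwich covariance with HC3 leverage
  correction: dose-response noise is multiplicative, and the classical
  homoskedastic covariance undercovered badly in simulation (59% over 200
  replicates versus 92% for HC3, against a 95% nominal level).  Saturation
  identifiability of the broken-merging fit is flagged from the fitted
  $c_2 \max Y_T$ and the width of the $c_2$ interval.
* **R²** (`goodness_of_fit()`, `ratio_response_fit()`): computed on
  replicate means with the intercept-included convention as canonical; a
  through-origin slope is reported alongside, since reported fits of this
  kind rarely state their convention.  Zero-variance tables return a degeneracy flag
  instead of an arbitrary number.
* **Ties and degenerate inputs**: `linear_range()` scans every contiguous
  window of ≥3 grid points (two points always fit a line), breaking ties
  towards wider, then denser, then lower windows; an empty result is a
  value, not an error.  Failed grid points in sweeps and generators are
  flagged `NA` and counted, never silently dropped.

## The synthetic-data generator

`generate_plate_dataset()` emulates steady-state GFP/OD plate-reader
measurements: the model output at each grid point times independent
lognormal factors (mean 1, CV `replicate_cv`, default 3 replicates);
`generate_flow_distribution()` emulates per-cell flow-cytometry readouts as
lognormal draws at the observed per-cell CV (≈0.5).  Noise is multiplicative
lognormal because the readouts are strictly positive with large CV; the
moment-matching parameterization is
$\sigma^2_{\log} = \log(1 + \mathrm{CV}^2)$,
$\mu_{\log} = \log(\mathrm{mean}) - \sigma^2_{\log}/2$.  Seeds are
mandatory and generation restores the caller's RNG state.  The generator
emulates a single steady-state read per replicate — no growth curves, batch
dilutions, autofluorescence or gating, and no replicate-level correlations;
a green parameter-recovery test therefore establishes estimator correctness
under this noise model, not robustness to every artefact of real plate data.

## Known limitations

* The full model's species set and the closed forms of $c_1, c_2$ are one
  principled construction from the circuit diagram and the standard
  resource-competition formalism; structurally different models (e.g. with
  explicit ribosome-mRNA complexes as state variables) could realize the
  same regime.
* Transcription is treated as resource-free (RNAP is not partitioned), so
  resource perturbations act purely translationally.
* No stochastic simulation, no spatial effects, no transient analysis beyond
  reaching steady state, and no growth-rate feedback on the ribosome pool.
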