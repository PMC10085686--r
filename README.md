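# mergenet

Modelling, analysis and fitting for the **incoherent merger network** — a
bacterial gene circuit that computes the *ratio* of two inducer signals at
the gene-expression output and is robust to fluctuations in shared cellular
resources.

## The problem

In the circuit, one inducer (Y; salicylate via the NahR activator) drives
production of an output protein P_Y, while a second inducer (X; IPTG via
LacI de-repression) drives a protease P_X that degrades P_Y through a
degradation tag.  Both productions draw on the same ribosome pool R, which
closes a type-I incoherent feedforward loop (R promotes both the output and
its degrader).  With mass-action kinetics

    dP_X/dt = k_X·X·R − a·P_X·P_Y + (b+k)·C − γ·P_X
    dP_Y/dt = k_Y·Y·R − a·P_X·P_Y + b·C     − γ·P_Y
    dC/dt   = a·P_X·P_Y − (b+k+γ)·C,        K = (b+k+γ)/a

and two operating assumptions — **A1**: P_Y ≪ K (first-order protease
regime) and **A2**: γ ≪ P_XT·(k+γ)/K (degradation beats dilution) — the
steady state collapses to the ratiometric law

    P_Y* = c·(Y/X),   c = γ·k_Y·K / ((k+γ)·k_X)

which is independent of R, proportional to Y/X, and tunable through the
output RBS strength (the TIR score is proportional to 1/K6, and c is
proportional to the TIR).  Removing the degradation tag ("broken merging")
destroys both properties: the output saturates in Y, responds to X only via
ribosome sequestration, and passes resource perturbations straight through.

The package is for circuit designers and modellers who want to (i) simulate
the full sensor/mRNA/ribosome-competition ODE model and its reduced laws,
(ii) check the operating assumptions and linear ranges, (iii) quantify
robustness and tunability, (iv) fit the reduced models to dose-response
data, and (v) generate realistic synthetic plate-reader and flow-cytometry
datasets for end-to-end pipeline testing.

## Worked example

```r
library(mergenet)

## the default circuit (strongest output RBS, TIR = 8875)
p  <- default_full_params(tir = 8875)
rc <- full_reduced_constants(p)
cat(sprintf("predicted ratiometric slope c: %.0f GFP/OD per unit Y/X\n", rc$c_gfp))
#> predicted ratiometric slope c: 220428 GFP/OD per unit Y/X

## are the reduction's assumptions satisfied at the worst operating point?
ss <- full_steady_state(p, inducer_pair(X = 50, Y = 20))
check_assumptions(full_reduced_constants(p, 50, 20)$merger, ss)
#> Assumption report (strictness 0.1):
#>   A1 (first-order protease, P_Y/K):            margin 0.006905  [pass]
#>   A2 (degradation >> dilution, gK/(P_XT(k+g))): margin 0.04513  [pass]

## robustness: halve the ribosome pool, watch the output barely move
rb <- resource_robustness(p, u = inducer_pair(50, 20), fraction = 0.5)
cat(sprintf("output change under a 50%% ribosome-pool drop: %.1f%%\n", rb$rel_pct_error))
#> output change under a 50% ribosome-pool drop: 4.2%

## synthetic plate data (3 replicates, 10% CV) and parameter recovery
ns  <- noise_spec(replicate_cv = 0.1, n_replicates = 3, seed = 1)
tab <- generate_plate_dataset(
  function(X, Y) reduced_merger_output(rc$c_gfp, list(X = X, Y = Y)),
  default_iptg_grid(), setdiff(default_sal_grid(), 0), ns)
fit_reduced_merger(tab, seed = 1)
#> Fit (c): converged, SSR = 5.59354e+08, R^2 = 0.99521
#>   c = 230245 [219747, 240742]

## tunability: predicted slope after weakening the output RBS
tir_scaled_slope(rc$c_gfp, TIR_ref = 8875, TIR_new = 4575)
#> [1] 113629.1
```

Reading the numbers: the full ODE model predicts a ratiometric slope of
220,428 GFP/OD per unit ratio; both operating margins sit well below the 0.1
strictness, so the closed-form law applies; halving the shared ribosome pool
moves the output by only ~4% (the broken-merging control changes exactly
2-fold under the same perturbation); a noisy synthetic dataset recovers the
generating slope within its 95% interval; and weakening the output RBS from
TIR 8875 to 4575 rescales the slope proportionally to 113,629.

## Command line

Each pipeline stage is also a CLI command writing CSV/JSON artifacts plus a
run manifest:

```sh
Rscript inst/scripts/mergenet synth --variant reduced-merger --seed 11 --out out/
Rscript inst/scripts/mergenet fit --in out/synth.csv --out out/
Rscript inst/scripts/mergenet robustness --perturbation 0.5 --out out/
Rscript inst/scripts/mergenet foldmap --atc 40 --out out/
Rscript inst/scripts/mergenet check-assumptions --x 50 --y 20 --out out/
```

(After installation the launcher lives at
`system.file("scripts", "mergenet", package = "mergenet")`.)

## Layout

- `R/` — merger core & reduced laws, steady-state solver, full circuit
  model, sensors & resource pool, analysis pipeline, model fitting,
  synthetic data, IO and CLI.
- `tests/testthat/` — unit and property tests with independent algebraic
  oracles, plus `test-acceptance.R` (one test per acceptance criterion).
- `vignettes/incoherent-merger.Rmd` — the model, assumptions, parameter
  choices and numerical decisions in detail.
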