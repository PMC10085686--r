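# Shared fixtures.  All data are built in code; no files are read.

# a small, well-conditioned merger parameter set (K = 1 uM)
fix_merger_params <- function(...) {
  args <- list(k_X = 0.01, k_Y = 0.03, a = 121, b = 10, k = 110,
               gamma = 1, P_XT = 0.5)
  args[names(list(...))] <- list(...)
  do.call(merger_params, args)
}

# the three equal-ratio inducer pairs used in the constant-ratio analysis
# (ratio 0.4: IPTG 50/75/100 uM with matched salicylate)
fix_ratio_pairs <- function() {
  list(inducer_pair(50, 20), inducer_pair(75, 30), inducer_pair(100, 40))
}

# reduced-merger model callable in GFP units
fix_reduced_model <- function(c = 220428) {
  function(X, Y) reduced_merger_output(c, list(X = X, Y = Y))
}

# a noiseless reduced-model table over the default grids (Y = 0 included)
fix_reduced_table <- function(c = 1000) {
  dose_response_sweep(fix_reduced_model(c), default_iptg_grid(),
                      default_sal_grid())
}

# coarse grids to keep full-model sweeps cheap in unit tests
fix_small_X <- function() c(50, 150, 400)
fix_small_Y <- function() c(5, 20, 50)
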