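test_that("dose_response_table validates keys and outputs", {
  expect_error(dose_response_table(c(1, 1), c(2, 2), c(1, 1), c(3, 4)),
               "duplicate")
  expect_error(dose_response_table(1, 2, 1, -3), "non-negative")
  t <- dose_response_table(c(1, 1), c(2, 2), c(1, 2), c(3, NA))
  expect_equal(attr(t, "n_failed"), 1L)
})

test_that("dose_response_sweep evaluates grids and survives failures", {
  model <- fix_reduced_model(c = 100)
  t1 <- dose_response_sweep(model, 50, 20)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$output, model(50, 20))
  # fixed X: proportional in Y; fixed Y: proportional in 1/X
  tY <- dose_response_sweep(model, 100, c(10, 20, 40))
  expect_equal(tY$output / tY$Y_uM, rep(1, 3))
  tX <- dose_response_sweep(model, c(50, 100, 200), 20)
  expect_equal(tX$output * tX$X_uM, rep(2000, 3))
  # model failure flags the row, the sweep continues
  flaky <- function(X, Y) if (X == 100) stop("boom") else X + Y
  tf <- dose_response_sweep(flaky, c(50, 100, 200), 10)
  expect_equal(attr(tf, "n_failed"), 1L)
  expect_true(is.na(tf$output[tf$X_uM == 100]))
  expect_equal(tf$output[tf$X_uM == 200], 210)
})

test_that("ratio_response_fit is exact on noiseless ratiometric data", {
  t <- fix_reduced_table(c = 1000)
  fit <- ratio_response_fit(t)
  expect_equal(fit$slope, 1000, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_false(fit$degenerate)
})

test_that("ratio_response_fit flags degenerate zero-variance tables", {
  t <- dose_response_table(c(10, 10, 10), c(1, 2, 4), 1L, c(5, 5, 5))
  fit <- ratio_response_fit(t)
  expect_true(fit$degenerate)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
})

test_that("ratio_response_fit recovers the true slope from noisy data", {
  cc <- 220428
  ns <- noise_spec(replicate_cv = 0.1, n_replicates = 3, seed = 77)
  tab <- generate_plate_dataset(fix_reduced_model(cc), default_iptg_grid(),
                                setdiff(default_sal_grid(), 0), ns)
  fit <- ratio_response_fit(tab)
  ci <- fit$slope + c(-1, 1) * 1.96 * fit$slope_se
  expect_gt(cc, ci[1])
  expect_lt(cc, ci[2])
  expect_error(ratio_response_fit(dose_response_table(c(1, 2), c(1, 2),
                                                      1L, c(1, 2))),
               "3 distinct ratios")
})

test_that("tir_scaled_slope is pure proportionality", {
  expect_equal(tir_scaled_slope(100, 5, 5), 100)
  expect_equal(tir_scaled_slope(100, 5, 10), 200)
  expect_error(tir_scaled_slope(-1, 5, 10), "positive")
  expect_error(tir_scaled_slope(100, 0, 10), "positive")
})

test_that("relative_percent_error matches its definition and is scale-free", {
  expect_equal(relative_percent_error(100, 95), 5)
  expect_equal(relative_percent_error(3.7, 3.7), 0)
  set.seed(21)
  for (i in 1:10) {
    nom <- runif(1, 1, 100); per <- runif(1, 0, 100); al <- runif(1, 0.1, 50)
    expect_equal(relative_percent_error(al * nom, al * per),
                 relative_percent_error(nom, per))
  }
  expect_error(relative_percent_error(0, 1), "positive")
})

test_that("constant_ratio_test separates merging from broken merging", {
  pairs <- fix_ratio_pairs()
  sp <- constant_ratio_test(fix_reduced_model(220428), pairs)
  expect_equal(sp$max_rel_dev, 0)
  expect_equal(sp$ratio, 0.4)
  broken <- function(X, Y)
    broken_merging_output(10, 10, 1, c1 = 0.01, c2 = 0.1, X, Y)
  sp_b <- constant_ratio_test(broken, pairs)
  expect_gt(sp_b$max_rel_dev, 0)
  expect_equal(constant_ratio_test(fix_reduced_model(), pairs[1])$max_rel_dev, 0)
  expect_error(constant_ratio_test(fix_reduced_model(),
                                   list(inducer_pair(50, 20),
                                        inducer_pair(75, 31))),
               "common ratio")
})

test_that("fold_change_map reports unsigned fold changes >= 1", {
  ctx_a <- resource_context(R_tot = 10)
  ctx_b <- resource_context(R_tot = 10, perturbation_fraction = 0.5)
  broken_model <- function(X, Y, ctx)
    broken_merging_output(10, ctx$perturbation_fraction * ctx$R_tot, 1,
                          0.01, 0.1, X, Y)
  # identical contexts: all entries exactly 1
  fc_id <- fold_change_map(broken_model, fix_small_X(), fix_small_Y(),
                           ctx_a, ctx_a)
  expect_true(all(fc_id == 1))
  # halved pool on the resource-proportional law: exactly 2 everywhere
  fc2 <- fold_change_map(broken_model, fix_small_X(), fix_small_Y(),
                         ctx_a, ctx_b)
  expect_true(all(abs(fc2 - 2) < 1e-12))
  expect_equal(attr(fc2, "max_fold"), 2)
  # the reduced merger law is resource-independent: map identically 1;
  # zero outputs (Y = 0) are flagged undefined
  merger_model <- function(X, Y, ctx) reduced_merger_output(50, list(X = X, Y = Y))
  fc_m <- fold_change_map(merger_model, fix_small_X(), c(0, 20),
                          ctx_a, ctx_b)
  expect_true(all(is.na(fc_m[, "0"])))
  expect_true(all(fc_m[, "20"] == 1))
  expect_true(all(fc2 >= 1, na.rm = TRUE))
})
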