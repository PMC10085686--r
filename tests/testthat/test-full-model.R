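test_that("ribosome conservation holds at every rhs evaluation", {
  p <- default_full_params()
  ctx <- default_resource_context(aTc = 40)
  set.seed(5)
  for (i in 1:20) {
    s <- c(m_X = runif(1, 0, 0.1), m_Y = runif(1, 0, 0.1),
           P_X = runif(1, 0, 2), P_Y = runif(1, 0, 0.5), C = runif(1, 0, 1))
    R <- free_ribosomes(s, p, ctx)
    total <- as.numeric(R) + sum(attr(R, "allocations"))
    expect_equal(total, ctx$perturbation_fraction * ctx$R_tot,
                 tolerance = 1e-12)
  }
})

test_that("zero DNA copies silence the output", {
  p <- default_full_params()
  p$sensor_Y <- sensor_params(1, 4000, 4, dna_copies = 0, max_rate = 96,
                              mode = "activator")
  ss <- full_steady_state(p, inducer_pair(100, 50), check_unique = FALSE)
  expect_true(ss$converged)
  expect_equal(ss$state[["m_Y"]], 0, tolerance = 1e-12)
  expect_equal(ss$state[["P_Y"]], 0, tolerance = 1e-10)
})

test_that("full-model steady states match the algebraic oracle", {
  p <- default_full_params()
  for (u in list(inducer_pair(50, 5), inducer_pair(150, 25),
                 inducer_pair(400, 50))) {
    ss <- full_steady_state(p, u, check_unique = FALSE)
    expect_true(ss$converged)
    expect_equal(ss$state, oracle_full_steady(p, u), tolerance = 1e-6)
  }
  # with the competitor induced
  ctx <- default_resource_context(aTc = 40)
  ss <- full_steady_state(p, inducer_pair(100, 20), ctx, check_unique = FALSE)
  expect_equal(ss$state, oracle_full_steady(p, inducer_pair(100, 20), ctx),
               tolerance = 1e-6)
  # broken-merging variant
  pb <- default_full_params(protease_tag = FALSE)
  ssb <- full_steady_state(pb, inducer_pair(100, 20), check_unique = FALSE)
  expect_equal(ssb$state, oracle_full_steady(pb, inducer_pair(100, 20)),
               tolerance = 1e-6)
})

test_that("full model approaches the ratiometric law when A1/A2 hold", {
  p <- default_full_params()
  rc <- full_reduced_constants(p)
  # assumptions hold at strictness 0.1 at the worst corner of the grid
  rc50 <- full_reduced_constants(p, X_ref = 50, Y_ref = 50)
  ss50 <- full_steady_state(p, inducer_pair(50, 50), check_unique = FALSE)
  rep <- check_assumptions(rc50$merger, ss50, strictness = 0.1)
  expect_true(rep$A1$pass)
  expect_true(rep$A2$pass)
  # spot agreement within 5% (grid-wide agreement is in the acceptance suite)
  for (u in list(inducer_pair(50, 50), inducer_pair(150, 25),
                 inducer_pair(400, 5))) {
    full <- full_steady_output(p, u, units = "uM", check_unique = FALSE)
    red <- reduced_merger_output(rc$c, u)
    expect_lt(abs(full - red) / red, 0.05)
  }
})

test_that("reduced/full discrepancy shrinks as the protease strengthens", {
  # stronger catalysis k at fixed K = 1 uM (a rescaled accordingly)
  err_at_k <- function(kcat) {
    p <- default_full_params()
    p$k <- kcat
    p$a <- (p$b + kcat + p$gamma) / 1
    u <- inducer_pair(50, 50)
    rc <- full_reduced_constants(p)
    full <- full_steady_output(p, u, units = "uM", check_unique = FALSE)
    red <- reduced_merger_output(rc$c, u)
    abs(full - red) / red
  }
  errs <- vapply(c(30, 110, 400), err_at_k, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("violating A2 breaks the reduced/full agreement", {
  p_bad <- default_full_params()
  p_bad$sensor_X <- sensor_params(10, 0.5, 0.00025, dna_copies = 0.1,
                                  max_rate = 119 / 30, mode = "repressor")
  u <- inducer_pair(50, 20)
  rc_bad <- full_reduced_constants(p_bad, X_ref = 50, Y_ref = 20)
  ss_bad <- full_steady_state(p_bad, u, check_unique = FALSE)
  rep <- check_assumptions(rc_bad$merger, ss_bad, strictness = 0.1)
  expect_false(rep$A2$pass)
  err_bad <- abs(ss_bad$state[["P_Y"]] - reduced_merger_output(rc_bad$c, u)) /
    reduced_merger_output(rc_bad$c, u)
  p_ok <- default_full_params()
  rc_ok <- full_reduced_constants(p_ok, X_ref = 50, Y_ref = 20)
  ss_ok <- full_steady_state(p_ok, u, check_unique = FALSE)
  err_ok <- abs(ss_ok$state[["P_Y"]] - reduced_merger_output(rc_ok$c, u)) /
    reduced_merger_output(rc_ok$c, u)
  expect_gt(err_bad, err_ok)
})

test_that("a 50% resource drop moves the full-model output by under 10%", {
  p <- default_full_params()
  rb <- resource_robustness(p, u = inducer_pair(100, 40), fraction = 0.5,
                            check_unique = FALSE)
  expect_lt(rb$rel_pct_error, 10)
  expect_gt(rb$rel_pct_error, 0)
})

test_that("full-model ratio invariance holds within 10% in the linear ranges", {
  p <- default_full_params()
  outs <- vapply(fix_ratio_pairs(), function(u)
    full_steady_output(p, u, check_unique = FALSE), numeric(1))
  expect_lt(max(abs(outs - mean(outs))) / mean(outs), 0.10)
})

test_that("sensitivity scales exactly with TIR via 1/K6", {
  p_ref <- default_full_params(tir = 8875)
  for (tir in c(4575, 1770)) {
    p_new <- default_full_params(tir = tir)
    expect_equal(p_ref$K6 / p_new$K6, tir / 8875, tolerance = 1e-12)
    expect_equal(full_reduced_constants(p_new)$c / full_reduced_constants(p_ref)$c,
                 tir / 8875, tolerance = 1e-12)
  }
})

test_that("broken-merging closed form tracks the full broken model", {
  pb <- default_full_params(protease_tag = FALSE)
  bc <- broken_reduced_constants(pb, X_ref = 150, Y_ref = 25)
  for (u in list(inducer_pair(50, 10), inducer_pair(150, 25),
                 inducer_pair(300, 50))) {
    full <- full_steady_output(pb, u, units = "uM", check_unique = FALSE)
    red <- broken_merging_output(bc$k6, bc$R_tot_eff, bc$gamma, bc$c1, bc$c2,
                                 u$X, u$Y)
    expect_equal(full, red, tolerance = 0.05)
  }
})
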