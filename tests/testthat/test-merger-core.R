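test_that("michaelis_constant evaluates (b + k + gamma)/a and validates", {
  expect_equal(michaelis_constant(a = 1, b = 0, k = 0, gamma = 1), 1)
  expect_equal(michaelis_constant(a = 2, b = 1, k = 2, gamma = 1), 2)
  # TIR proportionality pattern: halving a doubles K exactly
  K1 <- michaelis_constant(a = 14.2, b = 30, k = 40, gamma = 1)
  K2 <- michaelis_constant(a = 7.1, b = 30, k = 40, gamma = 1)
  expect_identical(K2, 2 * K1)
  expect_error(michaelis_constant(a = 0, b = 1, k = 1, gamma = 1),
               "positive")
  expect_error(michaelis_constant(a = 1, b = 0, k = 0, gamma = 0),
               "at least one")
})

test_that("merger_params validates rates and derives K", {
  p <- fix_merger_params()
  expect_s3_class(p, "merger_params")
  expect_equal(p$K, (10 + 110 + 1) / 121)
  expect_error(fix_merger_params(k_X = -1), "positive")
  expect_error(fix_merger_params(gamma = 0), "positive")
})

test_that("sensitivity_constant matches the closed form and its scalings", {
  # K = (0.5 + 9 + 1)/10.5 = 1, c = 1*10*1/((9+1)*1) = 1
  p <- merger_params(k_X = 1, k_Y = 10, a = 10.5, b = 0.5, k = 9, gamma = 1)
  expect_equal(sensitivity_constant(p), 1)
  # linear in k_Y (the RBS tuning knob)
  p2 <- merger_params(k_X = 1, k_Y = 20, a = 10.5, b = 0.5, k = 9, gamma = 1)
  expect_equal(sensitivity_constant(p2), 2 * sensitivity_constant(p))
  # property: re-derivation for random valid draws
  set.seed(42)
  for (i in 1:25) {
    q <- merger_params(k_X = runif(1, 1e-4, 10), k_Y = runif(1, 1e-4, 10),
                       a = runif(1, 1, 200), b = runif(1, 0.1, 50),
                       k = runif(1, 0.1, 200), gamma = runif(1, 0.1, 3))
    K <- (q$b + q$k + q$gamma) / q$a
    expect_equal(sensitivity_constant(q),
                 q$gamma * q$k_Y * K / ((q$k + q$gamma) * q$k_X))
  }
})

test_that("reduced_merger_output follows c*Y/X with exact ratio invariance", {
  expect_equal(reduced_merger_output(220428, inducer_pair(100, 40)), 88171.2)
  expect_equal(reduced_merger_output(5, inducer_pair(10, 0)), 0)
  expect_equal(reduced_merger_output(2, inducer_pair(1.5, 3)), 4)
  expect_error(reduced_merger_output(1, inducer_pair(0, 5)),
               "ratio undefined")
  # exact invariance under common scaling (up to fp rounding of the ratio)
  set.seed(7)
  for (i in 1:20) {
    X <- runif(1, 1, 500); Y <- runif(1, 0, 60); al <- runif(1, 0.01, 100)
    expect_equal(reduced_merger_output(3, list(X = al * X, Y = al * Y)),
                 reduced_merger_output(3, list(X = X, Y = Y)),
                 tolerance = 1e-14)
  }
})

test_that("merger_rhs implements the mass-action core", {
  p <- fix_merger_params()
  z <- c(P_X = 0, P_Y = 0, C = 0)
  expect_equal(merger_rhs(z, p, inducer_pair(0, 0), R = 5),
               c(P_X = 0, P_Y = 0, C = 0))
  expect_error(merger_rhs(c(P_X = -1, P_Y = 0, C = 0), p,
                          inducer_pair(1, 1), R = 1), "invalid state")
  # conservation: d(P_X + C)/dt = k_X*X*R - gamma*(P_X + C), independent of
  # the protease kinetics a, b, k
  set.seed(11)
  u <- inducer_pair(100, 30); R <- 4
  for (i in 1:20) {
    s <- c(P_X = runif(1, 0, 2), P_Y = runif(1, 0, 0.5), C = runif(1, 0, 1))
    q <- fix_merger_params(a = runif(1, 10, 300), b = runif(1, 1, 40),
                           k = runif(1, 10, 300))
    d <- merger_rhs(s, q, u, R)
    expect_equal(d[["P_X"]] + d[["C"]],
                 q$k_X * u$X * R - q$gamma * (s[["P_X"]] + s[["C"]]))
  }
})

test_that("broken_merging_output has the saturating non-ratiometric form", {
  expect_equal(broken_merging_output(10, 10, 1, 0.01, 0.1, X_T = 100, Y_T = 0), 0)
  # saturation limit at X_T = 0 is k6*R_tot/gamma
  lim <- broken_merging_output(10, 10, 1, 0.01, 0.1, X_T = 0, Y_T = 1e12)
  expect_equal(lim, 10 * 10 / 1, tolerance = 1e-9)
  # exact proportionality to R_tot at every input combination
  X <- c(50, 75, 100, 400); Y <- c(5, 20, 50, 50)
  full_pool <- broken_merging_output(10, 10, 1, 0.01, 0.1, X, Y)
  half_pool <- broken_merging_output(10, 5, 1, 0.01, 0.1, X, Y)
  expect_identical(full_pool, 2 * half_pool)
  # monotone: increasing in Y_T, decreasing in X_T
  ys <- broken_merging_output(10, 10, 1, 0.01, 0.1, 100, c(1, 5, 20, 50))
  expect_true(all(diff(ys) > 0))
  xs <- broken_merging_output(10, 10, 1, 0.01, 0.1, c(50, 100, 200, 400), 20)
  expect_true(all(diff(xs) < 0))
})

test_that("check_assumptions reports A1/A2 margins and boundary failures", {
  p <- fix_merger_params()  # K = 1, P_XT = 0.5
  ss <- structure(list(state = c(P_X = 0.4, P_Y = p$K / 100, C = 0.01),
                       converged = TRUE, residual_norm = 0,
                       method = "integration+root", unique = TRUE),
                  class = "steady_state_result")
  rep <- check_assumptions(p, ss, strictness = 0.1)
  expect_true(rep$A1$pass)
  expect_equal(rep$A1$margin, 0.01)
  expect_equal(rep$A2$margin, p$gamma * p$K / (p$P_XT * (p$k + p$gamma)))
  # A2 boundary: gamma == P_XT*(k+gamma)/K  =>  margin exactly 1, fails
  pb <- fix_merger_params(P_XT = p$gamma * p$K / (p$k + p$gamma))
  rep_b <- check_assumptions(pb, ss, strictness = 0.99)
  expect_equal(rep_b$A2$margin, 1)
  expect_false(rep_b$A2$pass)
  # unconverged input is an error
  ss_bad <- ss; ss_bad$converged <- FALSE
  expect_error(check_assumptions(p, ss_bad), "converge")
  expect_error(check_assumptions(p, ss, strictness = 1.2), "strictness")
})
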