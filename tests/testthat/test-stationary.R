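# Lyapunov covariances, conditional means, and the smoothed activation F.

test_that("solve_lyapunov handles closed-form cases and random systems", {
  expect_equal(unclass(solve_lyapunov(diag(3))), diag(3),
               ignore_attr = TRUE)
  a <- c(0.5, 2, 4)
  expect_equal(unclass(solve_lyapunov(diag(a))), diag(1 / a),
               ignore_attr = TRUE)
  A <- sample_intra_matrix(5, 0.9, seed = 2)
  D <- c(0.5, 1, 2, 1, 0.3)
  S <- solve_lyapunov(A, D)
  expect_lt(max(abs(A %*% S + S %*% t(A) - diag(2 * D))), 1e-10)
  expect_equal(S, t(S), ignore_attr = TRUE)
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(solve_lyapunov(diag(c(1, -1))), "not stable")
})

test_that("conditional means implement g A^{-1} phi", {
  A_t <- sample_intra_matrix(3, 0.5, seed = 4)
  W <- matrix(rnorm(3 * 4), 3, 4)
  x <- rnorm(4)
  for (scheme in c("summation", "integration")) {
    cp0 <- coupling_spec("I", "P", 0, W, scheme)
    expect_equal(conditional_mean(cp0, A_t, x), rep(0, 3))
    cp <- coupling_spec("I", "P", 1.7, W, scheme)
    expect_equal(conditional_mean(cp, A_t, x),
                 drop(1.7 * solve(A_t) %*% phi(cp, x)), tolerance = 1e-13)
  }
  cp1 <- coupling_spec("I", "O", 2, matrix(1), "summation")
  expect_equal(conditional_mean(cp1, matrix(1), 0.4), 2 * tanh(0.4))
  expect_error(conditional_mean(cp1, matrix(0), 0.4), "singular")
})

test_that("F agrees with its quadrature oracle on the whole working grid", {
  xs <- seq(-5, 5, length.out = 41)
  for (v in c(1e-4, 0.01, 0.1, 1, 5, 10)) {
    expect_lt(max(abs(F_series(xs, v) - F_quadrature(xs, v))), 1e-8)
  }
})

test_that("F has the analytic limits and qualitative properties", {
  expect_identical(F_series(0, 2.5), 0)
  expect_equal(F_series(3, 1e-13), tanh(3))
  expect_equal(F_series(3, 1e-9), tanh(3), tolerance = 1e-8)
  expect_equal(F_quadrature(c(-1, 0.5), 0), tanh(c(-1, 0.5)))
  xs <- seq(-5, 5, length.out = 41)
  for (v in c(1e-4, 0.01, 0.1, 1, 10)) {
    Fv <- F_series(xs, v)
    expect_true(all(abs(Fv) < 1))              # bounded
    expect_true(all(diff(Fv) > 0))             # increasing in x
    expect_equal(F_series(-xs, v), -Fv)        # odd
  }
  # smoothing damps the response: |F(x, v)| decreasing in v at fixed x != 0
  vs <- c(1e-4, 0.01, 0.1, 1, 5, 10)
  for (x in c(0.5, 2, 4)) {
    expect_true(all(diff(vapply(vs, function(v) F_series(x, v), 0)) < 0))
  }
})

test_that("F_quadrature matches a large Monte-Carlo average", {
  set.seed(10)
  z <- rnorm(1e6, mean = 2, sd = 2)
  mc <- mean(tanh(z))
  se <- sd(tanh(z)) / sqrt(length(z))
  expect_within_se(F_quadrature(2, 4), mc, se)
})

test_that("effective means reduce to conditional means as Sigma_P -> 0", {
  set.seed(12)
  M_P <- 3
  A_O <- matrix(1)
  A_OP <- matrix(rnorm(M_P), 1, M_P)
  A_P <- sample_intra_matrix(M_P, 0.5, seed = 3)
  m <- c(0.4, -0.9, 1.2)
  S0 <- diag(1e-14, M_P)
  cp_ns <- coupling_spec("P", "O", 2, A_OP, "summation")
  cp_int <- coupling_spec("P", "O", 2, A_OP, "integration")
  expect_equal(effective_mean_ns(2, A_O, A_OP, m, S0),
               conditional_mean(cp_ns, A_O, m), tolerance = 1e-7)
  expect_equal(effective_mean_int(2, A_O, A_OP, m, S0),
               conditional_mean(cp_int, A_O, m), tolerance = 1e-7)
  expect_equal(effective_mean_ns(0, A_O, A_OP, m, diag(M_P)), 0)
  expect_equal(effective_mean_int(0, A_O, A_OP, m, diag(M_P)), 0)
})

test_that("effective means equal the defining Monte-Carlo averages", {
  M_P <- 3
  A_O <- matrix(1)
  A_OP <- matrix(c(1.2, -0.7, 2.1), 1, M_P)
  A_P <- sample_intra_matrix(M_P, 0.9, seed = 5)
  Sigma_P <- solve_lyapunov(A_P)
  m <- c(0.3, -1.2, 0.8)
  g <- 2
  n <- 4e5
  set.seed(20)
  Xp <- sweep(matrix(rnorm(n * M_P), n, M_P) %*% chol(Sigma_P), 2, m, "+")
  for (scheme in c("summation", "integration")) {
    cp <- coupling_spec("P", "O", g, A_OP, scheme)
    draws <- conditional_mean(cp, A_O, Xp)
    mc <- mean(draws)
    se <- sd(draws) / sqrt(n)
    eff <- if (scheme == "summation")
      effective_mean_ns(g, A_O, A_OP, m, Sigma_P)
    else effective_mean_int(g, A_O, A_OP, m, Sigma_P)
    expect_within_se(eff, mc, se)
  }
})

test_that("sparse counts replace the dense normalization inside effective means", {
  M_P <- 4
  A_OP <- matrix(c(1, -2, 0, 0), 1, M_P)
  counts <- 2L
  Sigma_P <- diag(0.5, M_P)
  m <- c(0.2, -0.4, 9, 9)  # masked entries must not matter
  eff <- effective_mean_ns(3, matrix(1), A_OP, m, Sigma_P, counts = counts)
  manual <- 3 * (1 * F_series(0.2, 0.5) + (-2) * F_series(-0.4, 0.5)) / 2
  expect_equal(eff, manual, tolerance = 1e-12)
  eff_i <- effective_mean_int(3, matrix(1), A_OP, m, Sigma_P, counts = counts)
  v_int <- (1^2 + 2^2) * 0.5 / 4
  manual_i <- 3 * F_series((0.2 * 1 + (-0.4) * (-2)) / 2, v_int)
  expect_equal(eff_i, manual_i, tolerance = 1e-12)
})

test_that("factor chains have the regime-appropriate structure", {
  sys_np <- random_system(M_I = 4, g_OI = 1, seed = 2)
  f_np <- build_factorization(sys_np)
  expect_named(f_np$factors, c("I", "O"))
  expect_true(is.na(f_np$factors$I$conditioning))
  expect_identical(f_np$factors$O$conditioning, "I")

  sysf <- random_system(M_I = 4, M_P = 3, g_PI = 1, g_OP = 0,
                        scheme = "summation", regime = "fast_processing",
                        seed = 3)
  f_f <- build_factorization(sysf)
  # g_OP = 0: output factor has zero mean map and the Lyapunov covariance
  X <- matrix(rnorm(12), 3, 4)
  expect_equal(f_f$factors$O$mean_map(X), matrix(0, 3, 1))
  expect_equal(unclass(f_f$factors$O$Sigma),
               unclass(solve_lyapunov(sysf$units$O$A)), ignore_attr = TRUE)

  syss <- random_system(M_I = 4, M_P = 3, g_PI = 1, g_OP = 1,
                        scheme = "summation", regime = "slow_processing",
                        seed = 3)
  f_s <- build_factorization(syss)
  expect_identical(f_s$factors$O$conditioning, "P")  # Markov chain I->P->O

  # the input factor is shared by every regime
  for (f in list(f_f, f_s)) {
    expect_equal(unclass(f$factors$I$Sigma),
                 unclass(solve_lyapunov(f$system$units$I$A)),
                 ignore_attr = TRUE)
  }
})
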