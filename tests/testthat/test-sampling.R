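# Exact stationary sampling in the three timescale regimes.

test_that("uncoupled input and output sample independently with the right moments", {
  sys <- random_system(M_I = 3, g_OI = 0, seed = 5)
  fact <- build_factorization(sys)
  b <- sample_no_processing(sys, N = 20000, seed = 1, factorization = fact)
  # cross-covariance compatible with zero
  cc <- crossprod(scale(b$x_I, scale = FALSE), scale(b$x_O, scale = FALSE)) /
    (b$N - 1)
  expect_lt(max(abs(cc)), 3 * sqrt(3) / sqrt(b$N))
  # input covariance matches the Lyapunov solution
  emp <- cov(b$x_I)
  expect_lt(max(abs(emp - fact$factors$I$Sigma)), 4 / sqrt(b$N))
})

test_that("linear-stub sampling matches the closed-form Gaussian correlation", {
  sys <- random_system(M_I = 1, M_O = 1, g_OI = 1.2, sigma_OI = 1,
                       activation = "identity", seed = 8)
  # hand-computed linear response: x_O | x_I ~ N(g w x_I, 1) with w the
  # single (count-normalized) weight, Sigma_I = 1, Sigma_O = 1
  w <- sys$couplings$OI$Wn[1, 1]
  rho_true <- 1.2 * w / sqrt(1 + (1.2 * w)^2)
  b <- sample_no_processing(sys, N = 50000, seed = 2)
  rho_emp <- cor(b$x_I[, 1], b$x_O[, 1])
  expect_within_se(rho_emp, rho_true, (1 - rho_true^2) / sqrt(b$N))
})

test_that("fast-processing outputs sit on the effective conditional law", {
  sys <- random_system(M_I = 4, M_P = 3, g_PI = 1.5, g_OP = 2,
                       scheme = "integration", regime = "fast_processing",
                       seed = 9)
  fact <- build_factorization(sys)
  b <- sample_fast_processing(sys, N = 20000, seed = 3, factorization = fact)
  # conditional residuals have covariance Sigma_O
  resid <- b$x_O - fact$factors$O$mean_map(b$x_I)
  expect_within_se(var(resid[, 1]), fact$factors$O$Sigma[1, 1],
                   sqrt(2 / b$N) * fact$factors$O$Sigma[1, 1])
  expect_lt(abs(cor(resid[, 1], b$x_I[, 1])), 3 / sqrt(b$N))

  # g_OP = 0: outputs are pure stationary Gaussians
  sys0 <- random_system(M_I = 4, M_P = 3, g_PI = 1.5, g_OP = 0,
                        scheme = "integration", regime = "fast_processing",
                        seed = 9)
  f0 <- build_factorization(sys0)
  b0 <- sample_fast_processing(sys0, N = 20000, seed = 4, factorization = f0)
  expect_within_se(var(b0$x_O[, 1]), f0$factors$O$Sigma[1, 1],
                   sqrt(2 / b0$N) * f0$factors$O$Sigma[1, 1])
  expect_within_se(mean(b0$x_O[, 1]), 0, sqrt(f0$factors$O$Sigma[1, 1] / b0$N))
})

test_that("slow-processing nesting has the Markov structure", {
  sys <- random_system(M_I = 3, M_P = 2, g_PI = 0, g_OP = 2,
                       scheme = "summation", regime = "slow_processing",
                       seed = 11)
  b <- sample_slow_processing(sys, N_I = 150, N_inner = 120, seed = 5,
                              keep_P = TRUE)
  # broken chain: outputs decouple from the input...
  xI_rep <- b$x_I[rep(seq_len(b$N_I), each = b$N_inner), , drop = FALSE]
  expect_lt(max(abs(cor(xI_rep, b$x_O))), 0.03)
  # ...but still follow the processing unit
  expect_gt(abs(cor(b$x_P %*% sys$couplings$OP$Wn[1, ], b$x_O[, 1])), 0.1)
})

test_that("per-input conditional means match the defining average", {
  sys <- random_system(M_I = 3, M_P = 2, g_PI = 1.4, g_OP = 1.8,
                       scheme = "integration", regime = "slow_processing",
                       seed = 13)
  fact <- build_factorization(sys)
  b <- sample_slow_processing(sys, N_I = 5, N_inner = 4000, seed = 6,
                              factorization = fact)
  blocks <- matrix(b$x_O[, 1], nrow = b$N_inner)
  for (i in seq_len(b$N_I)) {
    # oracle: average m_OP over fresh draws of x_P ~ N(m_PI, Sigma_P)
    m_PI <- fact$factors$P$mean_map(b$x_I[i, , drop = FALSE])
    xp <- sweep(matrix(rnorm(4000 * 2), 4000, 2) %*% fact$factors$P$R,
                2, m_PI, "+")
    mo <- fact$factors$O$mean_map(xp)
    se <- sqrt((var(mo[, 1]) + fact$factors$O$Sigma[1, 1]) / 4000) * 2
    expect_within_se(mean(blocks[, i]), mean(mo[, 1]), se)
  }
})

test_that("pooled slow-regime moments are stable under doubling the inner count", {
  sys <- random_system(M_I = 3, M_P = 2, g_PI = 1.4, g_OP = 1.8,
                       scheme = "summation", regime = "slow_processing",
                       seed = 15)
  b1 <- sample_slow_processing(sys, N_I = 400, N_inner = 100, seed = 7)
  b2 <- sample_slow_processing(sys, N_I = 400, N_inner = 200, seed = 8)
  expect_lt(abs(var(b1$x_O[, 1]) - var(b2$x_O[, 1])),
            6 * var(b1$x_O[, 1]) / sqrt(400))
})

test_that("samplers are seed-reproducible and validate their regime", {
  sys <- random_system(M_I = 3, M_P = 2, g_PI = 1, g_OP = 1,
                       scheme = "summation", regime = "fast_processing",
                       seed = 20)
  a <- sample_fast_processing(sys, N = 100, seed = 9)
  b <- sample_fast_processing(sys, N = 100, seed = 9)
  expect_identical(a$x_O, b$x_O)
  expect_error(sample_no_processing(sys, N = 10, seed = 1), "regime")
  expect_error(sample_slow_processing(sys, 10, 10, seed = 1), "regime")
})

test_that("the slow regime obeys the data-processing inequality", {
  # I -> P -> O is Markov in the slow factorization, so I(I;O) <= I(I;P)
  sys <- random_system(M_I = 10, M_P = 1, M_O = 1, g_PI = 2, g_OP = 2,
                       sigma_P = 0, scheme = "integration",
                       regime = "slow_processing", seed = 33)
  fact <- build_factorization(sys)
  b <- sample_slow_processing(sys, N_I = 800, N_inner = 150, seed = 3,
                              factorization = fact, keep_P = TRUE)
  I_IO <- mi_slow(b)
  # I(I;P): the processing factor has closed-form conditional entropy
  H_P <- entropy_1d(b$x_P[, 1])
  I_IP <- H_P - gaussian_conditional_entropy(fact$factors$P$Sigma)
  se <- sqrt(I_IO$se_realizations^2 + 0.03^2)
  expect_lte(I_IO$value, I_IP + 3 * se)
})
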