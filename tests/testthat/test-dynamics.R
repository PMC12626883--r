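# Activation evaluation and Langevin integration.

test_that("the two schemes coincide for a single unit-weight source", {
  cp_ns <- coupling_spec("I", "O", 1, matrix(1), "summation")
  cp_int <- coupling_spec("I", "O", 1, matrix(1), "integration")
  expect_equal(phi(cp_ns, 0.7), tanh(0.7))
  expect_equal(phi(cp_int, 0.7), tanh(0.7))
})

test_that("phi vanishes at the bias point and matches the defining formula", {
  set.seed(3)
  W <- matrix(rnorm(3 * 5), 3, 5)
  theta <- rnorm(5)
  for (scheme in c("summation", "integration")) {
    cp <- coupling_spec("I", "O", 2, W, scheme, theta = theta)
    expect_equal(phi(cp, theta), rep(0, 3))
    x <- rnorm(5)
    # brute-force term-by-term evaluation
    manual <- vapply(1:3, function(i) {
      if (scheme == "summation") sum(W[i, ] * tanh(x - theta)) / 5
      else tanh(sum(W[i, ] * (x - theta)) / 5)
    }, numeric(1))
    expect_equal(phi(cp, x), manual, tolerance = 1e-14)
  }
})

test_that("sparse rows normalize by their connection count and C = 0 rows give 0", {
  W <- rbind(c(1, 2, 0, 0), c(0, 0, 0, 0))
  counts <- c(2L, 0L)
  x <- c(0.5, -1, 3, 2)
  cp <- coupling_spec("I", "O", 1, W, "summation", counts = counts)
  expect_equal(phi(cp, x),
               c((1 * tanh(0.5) + 2 * tanh(-1)) / 2, 0))
  cp2 <- coupling_spec("I", "O", 1, W, "integration", counts = counts)
  expect_equal(phi(cp2, x), c(tanh((0.5 - 2) / 2), 0))
})

test_that("phi is odd and bounded", {
  set.seed(8)
  W <- matrix(rnorm(4 * 6, sd = 2), 4, 6)
  for (scheme in c("summation", "integration")) {
    cp <- coupling_spec("I", "O", 1, W, scheme)
    for (r in 1:20) {
      x <- rnorm(6, sd = 3)
      expect_equal(phi(cp, -x), -phi(cp, x), tolerance = 1e-14)
      bound <- if (scheme == "integration") 1
               else max(rowSums(abs(W)) / 6)
      expect_true(all(abs(phi(cp, x)) <= bound + 1e-12))
    }
  }
})

test_that("drift matches element-wise evaluation of the equations of motion", {
  sys <- random_system(M_I = 3, M_P = 2, M_O = 1, g_PI = 1.3, g_OP = 0.7,
                       scheme = "integration", regime = "fast_processing",
                       seed = 21)
  expect_equal(drift(sys, numeric(6)), numeric(6))

  # single isolated 1-dof unit: drift = -x / tau
  iso <- system_spec(list(unit_spec("I", 1, matrix(1)),
                          unit_spec("O", 1, matrix(1))),
                     list(coupling_spec("I", "O", 0, matrix(0), "summation")))
  st <- drift(iso, c(2, 0))
  expect_equal(st[1], -2 / iso$units$I$tau)

  set.seed(4)
  x <- rnorm(6)
  d <- drift(sys, x)
  # manual evaluation per unit
  xI <- x[1:3]; xP <- x[4:5]; xO <- x[6]
  cpPI <- sys$couplings$PI; cpOP <- sys$couplings$OP
  dI <- -sys$units$I$A %*% xI / sys$units$I$tau
  dP <- (-sys$units$P$A %*% xP + cpPI$g * phi(cpPI, xI)) / sys$units$P$tau
  dO <- (-sys$units$O$A %*% xO + cpOP$g * phi(cpOP, xP)) / sys$units$O$tau
  expect_equal(d, c(dI, dP, dO), tolerance = 1e-13)
})

test_that("negating the state negates the drift when biases vanish", {
  sys <- random_system(M_I = 3, M_P = 2, M_O = 1, g_PI = 2, g_OP = 1,
                       scheme = "summation", regime = "slow_processing",
                       seed = 31)
  set.seed(5)
  for (r in 1:5) {
    x <- rnorm(6)
    expect_equal(drift(sys, -x), -drift(sys, x), tolerance = 1e-13)
  }
})

test_that("an isolated unit relaxes to its Lyapunov covariance", {
  # 1-dof Ornstein-Uhlenbeck: stationary variance D/A = 1
  iso <- system_spec(list(unit_spec("I", 1, matrix(1)),
                          unit_spec("O", 1, matrix(1))),
                     list(coupling_spec("I", "O", 0, matrix(0), "summation")))
  tr <- simulate_langevin(iso, n_keep = 4000, method = "euler", seed = 2)
  v <- var(tr$states$I[, 1])
  expect_within_se(v, 1, sqrt(2 / 4000) + 0.02)  # MC error + O(dt) bias

  # 2-dof unit, both integrators, against the Lyapunov oracle
  A <- sample_intra_matrix(2, 0.8, seed = 3)
  sys2 <- system_spec(list(unit_spec("I", 2, A), unit_spec("O", 1, matrix(1))),
                      list(coupling_spec("I", "O", 0, matrix(0, 1, 2),
                                         "summation")))
  S <- solve_lyapunov(A)
  for (m in c("euler", "splitting")) {
    tr2 <- simulate_langevin(sys2, n_keep = 4000, method = m, seed = 4)
    emp <- cov(tr2$states$I)
    expect_lt(max(abs(emp - S)), 0.1)
  }
})

test_that("halving dt changes stationary moments by less than the MC error", {
  A <- sample_intra_matrix(2, 0.8, seed = 13)
  sys2 <- system_spec(list(unit_spec("I", 2, A), unit_spec("O", 1, matrix(1))),
                      list(coupling_spec("I", "O", 1.5, matrix(c(1, -1), 1, 2),
                                         "integration")))
  taus <- vapply(sys2$units, function(u) u$tau, numeric(1))
  v <- vapply(c(40, 80), function(k) {
    tr <- simulate_langevin(sys2, dt = min(taus) / k, n_keep = 3000,
                            method = "euler", seed = 6)
    var(tr$states$O[, 1])
  }, numeric(1))
  expect_lt(abs(v[1] - v[2]), 3 * sqrt(2 / 3000) * max(v))
})

test_that("the integrator is seed-reproducible and guards against divergence", {
  sys <- random_system(M_I = 2, g_OI = 1, seed = 17)
  a <- simulate_langevin(sys, n_keep = 50, seed = 3)
  b <- simulate_langevin(sys, n_keep = 50, seed = 3)
  expect_identical(a$states, b$states)
  expect_error(simulate_langevin(sys, n_keep = 50, seed = 3, guard = 1e-4),
               "diverged.*step")
})
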