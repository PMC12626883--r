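# Shared fixtures and independent oracles.
#
# The closed-form Gaussian-chain mutual informations below are computed by
# plain covariance algebra, independently of the package's samplers and
# entropy estimators: with the identity activation every conditional mean
# is linear, so the joint law is Gaussian and
# I = (1/2) log2(det(Var[x_O]) / det(Var[x_O | conditioning])).

lin_response <- function(cp, A_target) {
  cp$g * solve(A_target) %*% cp$Wn
}

lin_mi_np <- function(sys) {
  f <- build_factorization(sys)
  B <- lin_response(sys$couplings$OI, sys$units$O$A)
  SI <- f$factors$I$Sigma
  SO <- f$factors$O$Sigma
  0.5 * log2(det(SO + B %*% SI %*% t(B)) / det(SO))
}

lin_mi_fast <- function(sys) {
  f <- build_factorization(sys)
  B <- lin_response(sys$couplings$OP, sys$units$O$A) %*%
    lin_response(sys$couplings$PI, sys$units$P$A)
  SI <- f$factors$I$Sigma
  SO <- f$factors$O$Sigma
  0.5 * log2(det(SO + B %*% SI %*% t(B)) / det(SO))
}

lin_mi_slow <- function(sys) {
  f <- build_factorization(sys)
  BO <- lin_response(sys$couplings$OP, sys$units$O$A)
  BP <- lin_response(sys$couplings$PI, sys$units$P$A)
  SI <- f$factors$I$Sigma
  SP <- f$factors$P$Sigma
  SO <- f$factors$O$Sigma
  condv <- SO + BO %*% SP %*% t(BO)
  B <- BO %*% BP
  0.5 * log2(det(condv + B %*% SI %*% t(B)) / det(condv))
}

# Tiny two-unit test system with explicit matrices.
make_io_system <- function(M_I = 2, g = 1, scheme = "summation",
                           activation = "tanh", seed = 42, sigma_OI = 1,
                           M_O = 1) {
  random_system(M_I = M_I, M_O = M_O, g_OI = g, sigma_OI = sigma_OI,
                scheme = scheme, activation = activation, seed = seed)
}

expect_within_se <- function(estimate, truth, se, k = 3) {
  expect_lt(abs(estimate - truth), k * se + 1e-12)
}
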