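# Exact stationary solutions: Lyapunov covariances, conditional means,
# and the Gaussian-smoothed activation function F.

#' Solve the stationary Lyapunov equation `A S + S A' = 2 D`
#'
#' The stationary covariance of a linear Langevin unit with stable drift
#' `-A x` and diagonal diffusion `D`. Solved through the complex
#' eigendecomposition of `A` (`S = V Y V'` with
#' `Y_ij = C_ij / (lambda_i + lambda_j)`), followed by one residual
#' refinement step, which brings the residual to near machine precision
#' for the moderate dimensions used here.
#'
#' @param A stable square matrix.
#' @param D diagonal diffusion: positive vector or diagonal matrix
#'   (default identity).
#' @return Symmetric positive-definite matrix with attribute `"residual"`
#'   (max absolute entry of `A S + S A' - 2 D`).
#' @export
solve_lyapunov <- function(A, D = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("`A` must be square")
  M <- nrow(A)
  if (is.null(D)) D <- rep(1, M)
  if (!is.null(dim(D))) D <- diag(D)
  if (any(D <= 0)) stop("`D` must be positive diagonal")
  ev <- eigen(A)
  if (min(Re(ev$values)) <= 0)
    stop("`A` is not stable: eigenvalue with Re = ", min(Re(ev$values)))
  Vi <- solve(ev$vectors)
  denom <- outer(ev$values, ev$values, `+`)
  solve_once <- function(RHS) {
    C <- Vi %*% RHS %*% t(Vi)
    Y <- C / denom
    S <- ev$vectors %*% Y %*% t(ev$vectors)
    (Re(S) + t(Re(S))) / 2
  }
  S <- solve_once(diag(2 * D, nrow = M))
  # one Newton-style refinement squares the residual down
  resid_mat <- diag(2 * D, nrow = M) - (A %*% S + S %*% t(A))
  S <- S + solve_once(resid_mat)
  resid <- max(abs(diag(2 * D, nrow = M) - (A %*% S + S %*% t(A))))
  structure(S, residual = resid)
}

#' Conditional stationary mean of a driven unit
#'
#' For a target unit with intra-unit matrix `A_target` receiving the
#' activation drive of a frozen source state, the stationary conditional
#' mean is `g A_target^{-1} phi(x_source)`; the nonlinearity of the joint
#' density lives entirely in this mean.
#'
#' @param coupling a [coupling_spec()].
#' @param A_target intra-unit matrix of the target unit (invertible).
#' @param x_source source state vector, or `N x M_source` matrix.
#' @return Mean vector of length `M_target` (or `N x M_target` matrix).
#' @export
conditional_mean <- function(coupling, A_target, x_source) {
  Ainv <- tryCatch(solve(A_target),
                   error = function(e) stop("`A_target` is singular"))
  p <- phi(coupling, x_source)
  if (is.null(dim(p))) drop(coupling$g * (Ainv %*% p))
  else coupling$g * p %*% t(Ainv)
}

#' Gaussian-smoothed activation: series evaluation
#'
#' `F(x, v)` is the expectation of `tanh(z)` under `z ~ N(x, v)`. It is
#' evaluated from the closed alternating series
#' `F = erf(x / sqrt(2v)) + sum_n (-1)^n e^{2 n^2 v} [V_n^+ - V_n^-]`
#' with `V_n^{+/-} = e^{-/+ 2 n x} erfc((2 n v -/+ x)/sqrt(2v))`.
#' Each product is evaluated in the algebraically equivalent stabilized
#' form `e^{-x^2/(2v)} erfcx((2 n v -/+ x)/sqrt(2v))` (plus the explicit
#' reflection `2 e^{2 n^2 v - 2 n x}` when the erfc argument is negative),
#' which avoids the catastrophic overflow of the naive form for `v` above
#' a few units. Plain summation stops when the next term falls below
#' `tol`; if the terms decay too slowly (they fall off only as `1/n^2`
#' for large `v`), the partial series is resummed with the
#' Cohen-Rodriguez Villegas-Zagier acceleration for alternating series,
#' whose error decreases as `5.83^{-K}` in the number of terms `K`.
#'
#' @param x evaluation point(s); vectorized.
#' @param v Gaussian variance (single non-negative number). Below
#'   `1e-12` the analytic limit `tanh(x)` is returned.
#' @param tol truncation tolerance for plain summation.
#' @param n_max maximum number of series terms.
#' @return Values in `(-1, 1)`, same length as `x`.
#' @seealso [F_quadrature()] for the independent quadrature evaluation.
#' @export
F_series <- function(x, v, tol = 1e-12, n_max = 200L) {
  if (!is.numeric(v) || length(v) != 1 || v < 0)
    stop("`v` must be a single non-negative number")
  if (v < 1e-12) return(tanh(x))
  sgn <- sign(x)
  a <- abs(x)
  sq <- sqrt(2 * v)
  E <- exp(-a^2 / (2 * v))
  out <- 2 * pnorm(a / sqrt(v)) - 1  # erf(a / sqrt(2v))
  K_store <- min(n_max, 100L)
  terms <- matrix(0, length(a), K_store)
  last <- rep(Inf, length(a))
  converged_at <- rep(NA_integer_, length(a))
  for (n in seq_len(K_store)) {
    arg_p <- (2 * n * v - a) / sq
    arg_m <- (2 * n * v + a) / sq
    tm <- E * erfcx_pos(arg_m)
    tp <- numeric(length(a))
    pos <- arg_p >= 0
    if (any(pos)) tp[pos] <- E[pos] * erfcx_pos(arg_p[pos])
    if (any(!pos))
      tp[!pos] <- 2 * exp(2 * n^2 * v - 2 * n * a[!pos]) -
        E[!pos] * erfcx_pos(-arg_p[!pos])
    t_n <- tp - tm
    terms[, n] <- t_n
    newly <- is.na(converged_at) & t_n < tol
    converged_at[newly] <- n
    last <- t_n
    if (all(!is.na(converged_at))) {
      terms <- terms[, seq_len(n), drop = FALSE]
      break
    }
  }
  K <- ncol(terms)
  signs <- (-1)^seq_len(K)
  plain <- drop(terms %*% signs)
  need_accel <- is.na(converged_at)
  if (any(need_accel)) {
    if (K < 12L)
      stop("series not converged within n_max = ", n_max,
           " terms (last term magnitude ", max(last[need_accel]), ")")
    # CVZ acceleration of sum_{k>=0} (-1)^k a_k with a_k = terms[, k+1]
    d <- (3 + sqrt(8))^K
    d <- (d + 1 / d) / 2
    b <- -1
    cc <- -d
    s <- numeric(sum(need_accel))
    Ta <- terms[need_accel, , drop = FALSE]
    for (k in 0:(K - 1)) {
      cc <- b - cc
      s <- s + cc * Ta[, k + 1]
      b <- (k + K) * (k - K) * b / ((k + 0.5) * (k + 1))
    }
    plain[need_accel] <- -s / d
  }
  res <- pmin(pmax(out + plain, 0), 1)  # F(a) lies in [0, 1) for a >= 0
  res * sgn
}

#' Gaussian-smoothed activation: quadrature evaluation
#'
#' Independent evaluation of the Gaussian expectation of `tanh` with mean
#' `x` and variance `v`, used as the oracle for [F_series()]. Uses
#' adaptive Gauss-Kronrod quadrature on the whole real line
#' (`stats::integrate`), which keeps the absolute error at or below
#' `1e-10` for all `v <= 50`; fixed-order Gauss-Hermite rules lose
#' accuracy there because the poles of `tanh` at `+/- i pi/2` limit the
#' integrand's analyticity strip once `v` is large.
#'
#' @param x evaluation point(s); vectorized.
#' @param v Gaussian variance (single non-negative number).
#' @return Values in `(-1, 1)`, same length as `x`.
#' @export
F_quadrature <- function(x, v) {
  if (!is.numeric(v) || length(v) != 1 || v < 0)
    stop("`v` must be a single non-negative number")
  if (v < 1e-14) return(tanh(x))
  s <- sqrt(v)
  # centre the integrand (z = x + s t) so the adaptive rule always sees
  # the Gaussian peak at the origin, however narrow it is
  vapply(x, function(xi) {
    stats::integrate(function(t) tanh(xi + s * t) * dnorm(t),
                     lower = -Inf, upper = Inf,
                     rel.tol = 1e-12, abs.tol = 1e-13,
                     subdivisions = 400L)$value
  }, numeric(1))
}

# Dispatch: Gaussian average of the activation. For the identity stub the
# average of z ~ N(x, v) is x itself.
F_act <- function(x, v, activation, tol = 1e-12, n_max = 200L) {
  if (activation == "identity") return(x)
  F_series(x, v, tol = tol, n_max = n_max)
}

#' Effective conditional output mean under nonlinear summation
#'
#' In the fast-processing limit the processing fluctuations are averaged
#' out, and each source component's activation is smoothed independently:
#' component `k` contributes `F(m_PI_k, Sigma_P_kk)`, weighted by the
#' count-normalized rows of `A_OP` and mapped through `g A_O^{-1}`. Only
#' the diagonal of `Sigma_P` enters.
#'
#' @param g processing-to-output interaction strength.
#' @param A_O output intra-unit matrix.
#' @param A_OP output-from-processing interaction matrix.
#' @param m_PI conditional processing mean(s): vector of length `M_P` or
#'   `N x M_P` matrix.
#' @param Sigma_P stationary processing covariance.
#' @param counts per-row connection counts of `A_OP` (default dense).
#' @param theta processing bias (default 0).
#' @param activation `"tanh"` or `"identity"`.
#' @return Effective mean(s): vector of length `M_O` or `N x M_O` matrix.
#' @export
effective_mean_ns <- function(g, A_O, A_OP, m_PI, Sigma_P, counts = NULL,
                              theta = NULL, activation = "tanh") {
  A_OP <- as.matrix(A_OP)
  vec_in <- is.null(dim(m_PI))
  Mmat <- if (vec_in) matrix(m_PI, nrow = 1) else as.matrix(m_PI)
  M_P <- ncol(A_OP)
  if (ncol(Mmat) != M_P) stop("`m_PI` inconsistent with `A_OP`")
  if (is.null(counts)) counts <- rep(M_P, nrow(A_OP))
  if (is.null(theta)) theta <- rep(0, M_P)
  Wn <- A_OP / ifelse(counts > 0, counts, 1)
  Wn[counts == 0, ] <- 0
  Ainv <- tryCatch(solve(A_O), error = function(e) stop("`A_O` is singular"))
  Fm <- matrix(0, nrow(Mmat), M_P)
  dSig <- diag(as.matrix(Sigma_P))
  for (k in seq_len(M_P))
    Fm[, k] <- F_act(Mmat[, k] - theta[k], max(dSig[k], 0), activation)
  out <- g * Fm %*% t(Wn) %*% t(Ainv)
  if (vec_in) drop(out) else out
}

#' Effective conditional output mean under nonlinear integration
#'
#' The linear combination happens inside the activation, so the smoothing
#' acts on the *integrated* signal: mean `m_int = Wn (m_PI - theta)` and
#' variance `v_int = diag(Wn Sigma_P Wn')` (the full quadratic form, not
#' just the diagonal of `Sigma_P`), followed by `F` componentwise and
#' `g A_O^{-1}`.
#'
#' @inheritParams effective_mean_ns
#' @return Effective mean(s): vector of length `M_O` or `N x M_O` matrix.
#' @export
effective_mean_int <- function(g, A_O, A_OP, m_PI, Sigma_P, counts = NULL,
                               theta = NULL, activation = "tanh") {
  A_OP <- as.matrix(A_OP)
  vec_in <- is.null(dim(m_PI))
  Mmat <- if (vec_in) matrix(m_PI, nrow = 1) else as.matrix(m_PI)
  M_P <- ncol(A_OP)
  if (ncol(Mmat) != M_P) stop("`m_PI` inconsistent with `A_OP`")
  if (is.null(counts)) counts <- rep(M_P, nrow(A_OP))
  if (is.null(theta)) theta <- rep(0, M_P)
  Wn <- A_OP / ifelse(counts > 0, counts, 1)
  Wn[counts == 0, ] <- 0
  Ainv <- tryCatch(solve(A_O), error = function(e) stop("`A_O` is singular"))
  m_int <- sweep(Mmat, 2, theta) %*% t(Wn)
  V <- Wn %*% as.matrix(Sigma_P) %*% t(Wn)
  v_int <- diag(as.matrix(V))
  tol_neg <- -1e-10 * max(1, max(abs(v_int)))
  if (any(v_int < tol_neg))
    stop("negative integrated variance beyond round-off: Sigma_P is broken")
  v_int <- pmax(v_int, 0)
  Fm <- matrix(0, nrow(Mmat), nrow(A_OP))
  for (j in seq_len(nrow(A_OP)))
    Fm[, j] <- F_act(m_int[, j], v_int[j], activation)
  out <- g * Fm %*% t(Ainv)
  if (vec_in) drop(out) else out
}

#' Build the regime-appropriate stationary factor chain
#'
#' In the limits of well-separated timescales the stationary joint
#' density factorizes into conditional Gaussians whose covariances solve
#' each unit's Lyapunov equation and whose means carry the nonlinearity:
#'
#' * `no_processing`: `p_I  p_{O|I}` with mean `g_OI A_O^{-1} phi(x_I)`;
#' * `fast_processing`: `p_I  p_{P|I}  p_{O|I}^eff` with the effective
#'   output mean obtained by Gaussian-smoothing the processing
#'   fluctuations ([effective_mean_ns()] / [effective_mean_int()]);
#' * `slow_processing`: `p_I  p_{P|I}  p_{O|P}` — a Markov chain
#'   `I -> P -> O` whose output factor ignores the input.
#'
#' @param system a stable [system_spec()].
#' @param regime overrides the system's regime (optional).
#' @return An object of class `msinfo_factorization`: a list of factors,
#'   each with `target`, `conditioning`, `Sigma`, its upper Cholesky
#'   factor `R`, and `mean_map(X)` mapping an `N x M_cond` matrix of
#'   conditioning states to an `N x M_target` matrix of means.
#' @export
build_factorization <- function(system, regime = NULL) {
  stopifnot(inherits(system, "msinfo_system"))
  regime <- regime %||% system$regime
  units <- system$units
  Sig <- lapply(units, function(u) solve_lyapunov(u$A, u$D))
  factor_of <- function(target, conditioning, mean_map) {
    list(target = target, conditioning = conditioning,
         Sigma = Sig[[target]], R = chol(Sig[[target]]),
         mean_map = mean_map)
  }
  f_I <- factor_of("I", NA_character_, function(X)
    matrix(0, if (is.null(dim(X))) 1 else nrow(X), units$I$M))
  if (regime == "no_processing") {
    cp <- system$couplings$OI
    f_O <- factor_of("O", "I",
      function(X) conditional_mean(cp, units$O$A, X))
    factors <- list(I = f_I, O = f_O)
  } else {
    cpPI <- system$couplings$PI
    cpOP <- system$couplings$OP
    f_P <- factor_of("P", "I",
      function(X) conditional_mean(cpPI, units$P$A, X))
    if (regime == "fast_processing") {
      eff <- if (cpOP$scheme == "summation") effective_mean_ns
             else effective_mean_int
      Sigma_P <- Sig$P
      f_O <- factor_of("O", "I", function(X) {
        m_PI <- conditional_mean(cpPI, units$P$A, X)
        eff(cpOP$g, units$O$A, cpOP$W, m_PI, Sigma_P,
            counts = cpOP$counts, theta = cpOP$theta,
            activation = cpOP$activation)
      })
    } else {
      f_O <- factor_of("O", "P",
        function(X) conditional_mean(cpOP, units$O$A, X))
    }
    factors <- list(I = f_I, P = f_P, O = f_O)
  }
  structure(list(regime = regime, factors = factors, system = system),
            class = "msinfo_factorization")
}

#' @exportS3Method print msinfo_factorization
print.msinfo_factorization <- function(x, ...) {
  cat("Stationary factorization (", x$regime, "):\n", sep = "")
  for (f in x$factors) {
    cond <- if (is.na(f$conditioning)) "" else paste0(" | ", f$conditioning)
    cat(sprintf("  p(%s%s): M = %d, Lyapunov residual = %.2e\n",
                f$target, cond, nrow(f$Sigma),
                attr(f$Sigma, "residual")))
  }
  invisible(x)
}
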