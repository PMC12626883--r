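# Activation schemes and Langevin integration.

#' Evaluate an inter-unit activation
#'
#' Computes the coupling drive that a source unit exerts on each degree of
#' freedom of a target unit. Under *nonlinear summation* each (biased)
#' source signal is passed through the activation first and then linearly
#' combined, row `i` giving `(1/C_i) sum_j W_ij tanh(x_j - theta_j)`;
#' under *nonlinear integration* the linear combination happens first,
#' giving `tanh((1/C_i) sum_j W_ij (x_j - theta_j))`. `C_i` is the number
#' of connections feeding row `i` (the source dimension in the dense
#' case); rows with no connections return 0.
#'
#' @param coupling a [coupling_spec()].
#' @param x_source numeric vector of length `M_source`, or an
#'   `N x M_source` matrix of states (one per row).
#' @return A vector of length `M_target` (or an `N x M_target` matrix).
#' @export
phi <- function(coupling, x_source) {
  stopifnot(inherits(coupling, "msinfo_coupling"))
  vec_in <- is.null(dim(x_source))
  X <- if (vec_in) matrix(x_source, nrow = 1) else as.matrix(x_source)
  if (ncol(X) != ncol(coupling$W))
    stop("`x_source` has ", ncol(X), " columns; coupling expects ",
         ncol(coupling$W))
  act <- if (coupling$activation == "tanh") tanh else identity
  Xc <- sweep(X, 2, coupling$theta)
  out <- switch(coupling$scheme,
    summation   = act(Xc) %*% t(coupling$Wn),
    integration = act(Xc %*% t(coupling$Wn)))
  if (vec_in) drop(out) else out
}

#' Drift field of the full multiscale system
#'
#' Returns the deterministic part of the dynamics, per unit
#' `[-A_mu x_mu + sum_nu g_munu phi_munu(x_nu)] / tau_mu`, evaluated at a
#' concatenated state vector ordered as the units of the system (input,
#' then processing if present, then output). The input unit receives no
#' incoming coupling by construction.
#'
#' @param system a [system_spec()].
#' @param state numeric vector of length `sum(M_mu)`.
#' @return Numeric vector of the same length.
#' @export
drift <- function(system, state) {
  stopifnot(inherits(system, "msinfo_system"))
  idx <- state_index(system)
  if (length(state) != idx$total)
    stop("`state` must have length ", idx$total)
  out <- numeric(idx$total)
  for (lab in names(system$units)) {
    u <- system$units[[lab]]
    x_u <- state[idx$slice[[lab]]]
    d <- -drop(u$A %*% x_u)
    for (cp in system$couplings) {
      if (cp$target == lab)
        d <- d + cp$g * phi(cp, state[idx$slice[[cp$source]]])
    }
    out[idx$slice[[lab]]] <- d / u$tau
  }
  out
}

# Per-unit slices of the concatenated state vector.
state_index <- function(system) {
  Ms <- vapply(system$units, function(u) u$M, numeric(1))
  ends <- cumsum(Ms)
  starts <- c(1, head(ends, -1) + 1)
  slice <- Map(function(s, e) seq.int(s, e), starts, ends)
  names(slice) <- names(system$units)
  list(slice = slice, total = sum(Ms))
}

#' Integrate the Langevin dynamics of a multiscale system
#'
#' Simulates the coupled stochastic dynamics with additive noise of
#' amplitude `sqrt(2 tau_mu) sigma_mu` (so each isolated unit relaxes to
#' the Lyapunov covariance of its linear part). Two fixed-step methods are
#' available:
#'
#' * `"euler"` — plain Euler-Maruyama,
#'   `dx = drift dt + sqrt(2 dt / tau) sigma xi`. Requires
#'   `dt < min(tau)/10`.
#' * `"splitting"` — exponential (exact Ornstein-Uhlenbeck) splitting: the
#'   linear intra-unit part and its noise are propagated exactly over each
#'   step via the matrix exponential and the exact step covariance, while
#'   the nonlinear inter-unit drive is held constant across the step. The
#'   linear part is unconditionally stable, so steps only need to resolve
#'   the fastest unit's response to its (slower) drive; this makes stiff
#'   timescale ladders affordable. Requires `dt <= min(tau)/2`.
#'
#' @param system a stable [system_spec()].
#' @param dt integrator step. Default: `min(tau)/20` for `"euler"`,
#'   `min(tau)/5` for `"splitting"`.
#' @param n_keep number of post-burn-in samples to retain.
#' @param thin steps between retained samples; defaults to the slowest
#'   timescale over `dt`, so retained samples are approximately
#'   independent.
#' @param burn_in steps discarded before recording; defaults to
#'   `50 * max(tau) / dt`.
#' @param seed integer seed for the integrator's random stream.
#' @param method `"euler"` or `"splitting"`.
#' @param x0 initial concatenated state (default zero).
#' @param guard overflow guard: the integrator aborts (naming the first
#'   offending step) if any |state| exceeds this.
#' @return An object of class `msinfo_trajectory`: list with one
#'   `n_keep x M_mu` matrix per unit, retained times, and the
#'   configuration.
#' @export
simulate_langevin <- function(system, dt = NULL, n_keep = 1000, thin = NULL,
                              burn_in = NULL, seed = 1,
                              method = c("euler", "splitting"),
                              x0 = NULL, guard = 1e6) {
  stopifnot(inherits(system, "msinfo_system"))
  method <- match.arg(method)
  taus <- vapply(system$units, function(u) u$tau, numeric(1))
  if (is.null(dt))
    dt <- if (method == "euler") min(taus) / 20 else min(taus) / 5
  if (method == "euler" && dt >= min(taus) / 10)
    stop("Euler-Maruyama requires dt < min(tau)/10; got dt = ", dt)
  if (method == "splitting" && dt > min(taus) / 2)
    stop("splitting integrator requires dt <= min(tau)/2; got dt = ", dt)
  for (lab in names(system$units)) {
    st <- check_stability(system$units[[lab]]$A)
    if (!st$stable)
      stop("unit ", lab, " is linearly unstable (margin ", st$margin, ")")
  }
  if (is.null(thin)) thin <- max(1L, round(max(taus) / dt))
  if (is.null(burn_in)) burn_in <- ceiling(50 * max(taus) / dt)
  idx <- state_index(system)
  if (is.null(x0)) x0 <- numeric(idx$total)

  labs <- names(system$units)
  units_cpp <- lapply(labs, function(lab) {
    u <- system$units[[lab]]
    r <- dt / u$tau
    if (method == "euler") {
      list(M1 = diag(u$M) - r * u$A,
           M2 = diag(u$M) * r,
           L  = sqrt(2 * r) * chol_of(u$D))
    } else {
      Phi <- as.matrix(Matrix::expm(-r * u$A))
      Sst <- solve_lyapunov(u$A, u$D)
      Sstep <- Sst - Phi %*% Sst %*% t(Phi)
      Sstep <- (Sstep + t(Sstep)) / 2
      list(M1 = Phi,
           M2 = solve(u$A, diag(u$M) - Phi),
           L  = chol_psd(Sstep))
    }
  })
  coup_cpp <- lapply(system$couplings, function(cp) {
    list(target = match(cp$target, labs) - 1L,
         source = match(cp$source, labs) - 1L,
         g = cp$g, Wn = cp$Wn, theta = cp$theta,
         scheme = if (cp$scheme == "summation") 0L else 1L,
         act = if (cp$activation == "tanh") 0L else 1L)
  })
  Ms <- vapply(system$units, function(u) u$M, integer(1))
  res <- cpp_integrate(units_cpp, coup_cpp, as.integer(Ms), x0,
                       as.integer(n_keep), as.integer(thin),
                       as.integer(burn_in), guard, as.integer(seed))
  names(res) <- labs
  structure(list(states = res,
                 times = (burn_in + thin * seq_len(n_keep)) * dt,
                 dt = dt, thin = thin, burn_in = burn_in, method = method,
                 seed = seed),
            class = "msinfo_trajectory")
}

# Lower Cholesky factor of a diagonal-or-dense PSD matrix, tolerant of
# zero eigenvalues (the exact step covariance can be near-singular for
# very small steps).
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(vals), nrow = length(vals))
}

chol_of <- function(D) {
  if (is.null(dim(D))) diag(sqrt(D), nrow = length(D)) else t(chol(D))
}

#' @exportS3Method print msinfo_trajectory
print.msinfo_trajectory <- function(x, ...) {
  cat("Langevin trajectory (", x$method, "): ",
      nrow(x$states[[1]]), " retained samples, dt = ", format(x$dt),
      ", thin = ", x$thin, "\n", sep = "")
  invisible(x)
}
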