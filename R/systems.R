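# System specification objects: units, couplings, full architectures.

#' Specify one stochastic unit
#'
#' A unit is a group of `M` degrees of freedom sharing a timescale `tau`,
#' linearly coupled through `A` (drift `-A x / tau`) and driven by white
#' noise with diagonal diffusion `D` (identity by default).
#'
#' @param label one of `"I"`, `"P"`, `"O"`.
#' @param M number of degrees of freedom.
#' @param A `M x M` intra-unit coupling matrix; all eigenvalues must have
#'   strictly positive real part.
#' @param tau unit timescale (arbitrary units, positive).
#' @param D diagonal diffusion: a positive vector of length `M` or a
#'   positive diagonal matrix. Default identity.
#' @return An object of class `msinfo_unit`.
#' @export
unit_spec <- function(label, M, A, tau = 1, D = NULL) {
  label <- match.arg(label, c("I", "P", "O"))
  stopifnot(M >= 1, M == round(M), tau > 0)
  A <- as.matrix(A)
  if (nrow(A) != M || ncol(A) != M)
    stop("`A` must be ", M, " x ", M)
  if (is.null(D)) D <- rep(1, M)
  if (!is.null(dim(D))) {
    if (any(D[upper.tri(D) | lower.tri(D)] != 0))
      stop("`D` must be diagonal")
    D <- diag(D)
  }
  if (length(D) != M || any(D <= 0))
    stop("`D` must have ", M, " strictly positive diagonal entries")
  st <- check_stability(A)
  if (!st$stable)
    stop("unit ", label, " is unstable: min Re(eigenvalue) = ", st$margin)
  structure(list(label = label, M = as.integer(M), tau = tau, A = A, D = D),
            class = "msinfo_unit")
}

#' Specify a directed inter-unit coupling
#'
#' @param source,target unit labels (`"I"`, `"P"`, `"O"`).
#' @param g overall interaction strength.
#' @param W `M_target x M_source` interaction matrix (entries of absent
#'   connections must be exactly 0 when `counts` marks them sparse).
#' @param scheme `"summation"` or `"integration"`.
#' @param theta source bias vector (length `M_source`, default 0): the
#'   activation acts on `x - theta`.
#' @param counts per-target-row connection counts used to normalize the
#'   activation; defaults to `M_source` for every row (dense coupling).
#'   Rows with 0 connections contribute a zero drive.
#' @param activation `"tanh"` (the model's saturating nonlinearity) or
#'   `"identity"` (linear stub used for closed-form Gaussian validation).
#' @return An object of class `msinfo_coupling`. The field `Wn` caches the
#'   count-normalized matrix actually used by the activation.
#' @export
coupling_spec <- function(source, target, g, W,
                          scheme = c("summation", "integration"),
                          theta = NULL, counts = NULL,
                          activation = c("tanh", "identity")) {
  source <- match.arg(source, c("I", "P", "O"))
  target <- match.arg(target, c("I", "P", "O"))
  scheme <- match.arg(scheme)
  activation <- match.arg(activation)
  W <- as.matrix(W)
  if (is.null(theta)) theta <- rep(0, ncol(W))
  if (length(theta) != ncol(W))
    stop("`theta` must have length ", ncol(W))
  if (is.null(counts)) counts <- rep(ncol(W), nrow(W))
  counts <- as.integer(counts)
  if (length(counts) != nrow(W) || any(counts < 0))
    stop("`counts` must be ", nrow(W), " non-negative integers")
  Wn <- W / ifelse(counts > 0, counts, 1)
  Wn[counts == 0, ] <- 0
  structure(list(source = source, target = target, g = g, W = W,
                 scheme = scheme, theta = theta, counts = counts,
                 activation = activation, Wn = Wn),
            class = "msinfo_coupling")
}

#' Assemble a full multiscale system
#'
#' Supported architectures are the input-processing-output chain
#' (couplings `I -> P` and `P -> O`) and the direct input-output system
#' (`I -> O`). The input always evolves independently. Timescales are
#' assigned from the regime: the slowest unit (always the input) has
#' `tau = 1` and each successively faster unit is a factor `delta_tau`
#' faster. Fast processing means `tau_I >> tau_O >> tau_P`; slow
#' processing means `tau_I >> tau_P >> tau_O`; without a processing unit
#' only `tau_I >> tau_O` is needed.
#'
#' @param units named list of [unit_spec()]s (`I`, optionally `P`, `O`).
#' @param couplings list of [coupling_spec()]s.
#' @param regime `"no_processing"`, `"fast_processing"` or
#'   `"slow_processing"`; inferred as `"no_processing"` when there is no
#'   processing unit.
#' @param delta_tau successive timescale ratio (default `1e-2`).
#' @return An object of class `msinfo_system`.
#' @export
system_spec <- function(units, couplings,
                        regime = NULL, delta_tau = 1e-2) {
  labs <- vapply(units, function(u) u$label, character(1))
  names(units) <- labs
  if (!("I" %in% labs) || !("O" %in% labs))
    stop("system needs at least an input and an output unit")
  has_P <- "P" %in% labs
  if (is.null(regime)) {
    if (!has_P) regime <- "no_processing"
    else stop("`regime` must be given for a system with a processing unit")
  }
  regime <- match.arg(regime,
    c("no_processing", "fast_processing", "slow_processing"))
  keys <- vapply(couplings, function(cp) paste0(cp$target, cp$source),
                 character(1))
  names(couplings) <- keys
  expected <- if (has_P) c("PI", "OP") else "OI"
  if (!setequal(keys, expected))
    stop("architecture requires couplings {", paste(expected, collapse = ", "),
         "}; got {", paste(keys, collapse = ", "), "}")
  if (has_P && regime == "no_processing")
    stop("`no_processing` regime is incompatible with a processing unit")
  for (cp in couplings) {
    if (nrow(cp$W) != units[[cp$target]]$M ||
        ncol(cp$W) != units[[cp$source]]$M)
      stop("coupling ", cp$target, "<-", cp$source,
           " has dimensions inconsistent with its units")
  }
  stopifnot(delta_tau > 0, delta_tau < 1)
  ladder <- switch(regime,
    no_processing   = c(I = 1, O = delta_tau),
    fast_processing = c(I = 1, O = delta_tau, P = delta_tau^2),
    slow_processing = c(I = 1, P = delta_tau, O = delta_tau^2))
  # canonical unit order: architecture order I, P, O
  units <- units[intersect(c("I", "P", "O"), names(units))]
  for (lab in names(units)) units[[lab]]$tau <- ladder[[lab]]
  structure(list(units = units, couplings = couplings, regime = regime,
                 delta_tau = delta_tau),
            class = "msinfo_system")
}

#' @exportS3Method print msinfo_system
print.msinfo_system <- function(x, ...) {
  cat("Multiscale system (", x$regime, ")\n", sep = "")
  for (u in x$units)
    cat(sprintf("  unit %s: M = %d, tau = %g\n", u$label, u$M, u$tau))
  for (cp in x$couplings)
    cat(sprintf("  %s -> %s: g = %g, %s (%s)%s\n", cp$source, cp$target,
                cp$g, cp$scheme, cp$activation,
                if (any(cp$counts < ncol(cp$W))) " [sparse]" else ""))
  invisible(x)
}

#' Draw a random system from the Gaussian interaction ensembles
#'
#' Intra-unit matrices have unit diagonal and Gaussian off-diagonal
#' entries of standard deviation `sigma_mu / sqrt(M_mu)` (rejection
#' sampled until linearly stable, advancing the seed); inter-unit matrices
#' have i.i.d. `N(0, sigma_munu^2)` entries, optionally thinned by a
#' Bernoulli(`p_unit`) connection mask. With `M_P = NULL` the system is
#' the direct input-output architecture driven by `g_OI`.
#'
#' @param M_I,M_P,M_O unit dimensions (`M_P = NULL` for no processing).
#' @param g_PI,g_OP,g_OI interaction strengths for the couplings present.
#' @param scheme activation scheme for all couplings.
#' @param regime timescale regime (required when `M_P` is given).
#' @param sigma_I,sigma_P,sigma_O intra-unit heterogeneities.
#' @param sigma_PI,sigma_OP,sigma_OI inter-unit heterogeneities.
#' @param p_unit inter-unit connection probability.
#' @param topology_P `"dense"` or `"barabasi_albert"` processing topology.
#' @param ba_attachment edges per new node for the BA topology.
#' @param theta_sd if positive, each coupling gets a random source bias
#'   with entries `N(0, theta_sd^2)`.
#' @param activation `"tanh"` or `"identity"` (validation stub).
#' @param delta_tau successive timescale ratio.
#' @param seed integer seed (drives all draws reproducibly).
#' @param min_margin minimal stability margin accepted for intra-unit
#'   draws (0 keeps the plain stability condition).
#' @param max_tries rejection budget per intra-unit matrix.
#' @return An `msinfo_system`; the attribute `"rejections"` counts
#'   discarded unstable intra-unit draws.
#' @export
random_system <- function(M_I, M_P = NULL, M_O = 1,
                          g_PI = 1, g_OP = 1, g_OI = 1,
                          scheme = c("summation", "integration"),
                          regime = NULL,
                          sigma_I = 0.9, sigma_P = 0.9, sigma_O = 0,
                          sigma_PI = 1, sigma_OP = 1, sigma_OI = 1,
                          p_unit = 1, topology_P = "dense",
                          ba_attachment = 2L, theta_sd = 0,
                          activation = c("tanh", "identity"),
                          delta_tau = 1e-2, seed = NULL,
                          min_margin = 0, max_tries = 100L) {
  scheme <- match.arg(scheme)
  activation <- match.arg(activation)
  rej <- 0L
  sub <- function(k) if (is.null(seed)) NULL else derive_seed(seed, k)
  draw_A <- function(M, sigma, k, topology = "dense") {
    A <- sample_stable_intra(M, sigma, seed = sub(k), topology = topology,
                             attachment = ba_attachment,
                             max_tries = max_tries, min_margin = min_margin)
    rej <<- rej + attr(A, "rejections")
    attr(A, "rejections") <- NULL
    A
  }
  draw_theta <- function(M, k) {
    if (theta_sd <= 0) return(NULL)
    with_seed(sub(k), rnorm(M, sd = theta_sd))
  }
  uI <- unit_spec("I", M_I, draw_A(M_I, sigma_I, 1L))
  uO <- unit_spec("O", M_O, draw_A(M_O, sigma_O, 2L))
  if (is.null(M_P)) {
    w <- sample_inter_matrix(M_O, M_I, sigma_OI, p_unit, seed = sub(3L))
    cps <- list(coupling_spec("I", "O", g_OI, w$W, scheme,
                              theta = draw_theta(M_I, 6L),
                              counts = w$counts, activation = activation))
    sys <- system_spec(list(uI, uO), cps, regime = regime %||% "no_processing",
                       delta_tau = delta_tau)
  } else {
    if (is.null(regime))
      stop("`regime` is required when a processing unit is present")
    uP <- unit_spec("P", M_P, draw_A(M_P, sigma_P, 4L, topology = topology_P))
    wPI <- sample_inter_matrix(M_P, M_I, sigma_PI, p_unit, seed = sub(3L))
    wOP <- sample_inter_matrix(M_O, M_P, sigma_OP, p_unit, seed = sub(5L))
    cps <- list(
      coupling_spec("I", "P", g_PI, wPI$W, scheme,
                    theta = draw_theta(M_I, 6L),
                    counts = wPI$counts, activation = activation),
      coupling_spec("P", "O", g_OP, wOP$W, scheme,
                    theta = draw_theta(M_P, 7L),
                    counts = wOP$counts, activation = activation))
    sys <- system_spec(list(uI, uP, uO), cps, regime = regime,
                       delta_tau = delta_tau)
  }
  attr(sys, "rejections") <- rej
  sys
}

#' Summarize stability margins and stationary covariance residuals
#'
#' @param system an `msinfo_system`.
#' @return A data frame, one row per unit, with the stability margin and
#'   the Lyapunov residual of the stationary covariance (invisibly);
#'   printed as a side effect.
#' @export
describe_system <- function(system) {
  stopifnot(inherits(system, "msinfo_system"))
  rows <- lapply(system$units, function(u) {
    st <- check_stability(u$A)
    S <- solve_lyapunov(u$A, u$D)
    data.frame(unit = u$label, M = u$M, tau = u$tau,
               stability_margin = st$margin,
               lyapunov_residual = attr(S, "residual"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  print(out)
  invisible(out)
}
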