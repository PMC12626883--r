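# Entropy, mutual information, and bimodality diagnostics.

#' Differential entropy of a one-dimensional sample
#'
#' Default estimator is the Kozachenko-Leonenko k-nearest-neighbour
#' estimator with `k = 4`:
#' `H = psi(n) - psi(k) + log(2) + mean(log eps_i)` (in nats, converted
#' to bits), where `eps_i` is the distance from sample `i` to its k-th
#' nearest neighbour. It is consistent with a mild negative bias of order
#' `1/n` for smooth densities. The `"histogram"` alternative is the
#' plug-in estimator on Freedman-Diaconis bins, retained as a
#' cross-check; the two agree within a few hundredths of a bit on smooth
#' unimodal fixtures at `n = 1e5`.
#'
#' @param x numeric vector, at least 100 finite samples.
#' @param estimator `"knn"` or `"histogram"`.
#' @param k neighbour order for the knn estimator.
#' @return Entropy in bits. A zero-variance sample returns `-Inf` with
#'   attribute `degenerate = TRUE`.
#' @export
entropy_1d <- function(x, estimator = c("knn", "histogram"), k = 4L) {
  estimator <- match.arg(estimator)
  x <- as.numeric(x)
  if (length(x) < 100) stop("need at least 100 samples")
  if (any(!is.finite(x))) stop("samples must be finite")
  if (var(x) == 0)
    return(structure(-Inf, degenerate = TRUE))
  if (estimator == "knn") {
    n <- length(x)
    eps <- knn_dist_1d(sort(x), k)
    # exact ties give zero radii; nudge them to the smallest resolvable
    # scale so the log stays finite
    if (any(eps == 0)) {
      floor_eps <- max(.Machine$double.eps * max(abs(x), 1), min(eps[eps > 0]))
      eps[eps == 0] <- floor_eps
    }
    H_nats <- digamma(n) - digamma(k) + log(2) + mean(log(eps))
    H_nats / log(2)
  } else {
    h <- graphics::hist(x, breaks = "FD", plot = FALSE)
    p <- h$counts / length(x)
    w <- diff(h$breaks)
    keep <- p > 0
    -sum(p[keep] * log2(p[keep] / w[keep]))
  }
}

# Distance to the k-th nearest neighbour for each element of a *sorted*
# vector: the k-th NN of x_(i) lies among its k predecessors/successors,
# so only a 2k-column band of gaps has to be searched.
knn_dist_1d <- function(xs, k) {
  n <- length(xs)
  if (n <= k) stop("need more than k samples")
  cols <- vector("list", 2L * k)
  for (j in seq_len(k)) {
    right <- c(xs[-seq_len(j)], rep(Inf, j)) - xs
    left <- xs - c(rep(-Inf, j), xs[seq_len(n - j)])
    cols[[j]] <- right
    cols[[k + j]] <- left
  }
  Dm <- do.call(cbind, cols)
  m <- numeric(n)
  for (t in seq_len(k)) {  # extract the running minimum k times
    jmin <- max.col(-Dm, ties.method = "first")
    id <- cbind(seq_len(n), jmin)
    m <- Dm[id]
    Dm[id] <- Inf
  }
  m
}

#' Closed-form conditional entropy of a Gaussian factor
#'
#' The conditional output density has an input-independent covariance, so
#' its differential entropy is the Gaussian closed form
#' `h = (1/2) log2((2 pi e)^M det Sigma)` bits.
#'
#' @param Sigma positive-definite covariance matrix (or scalar).
#' @param M_O dimension (defaults to `nrow(Sigma)`).
#' @return Entropy in bits.
#' @export
gaussian_conditional_entropy <- function(Sigma, M_O = NULL) {
  Sigma <- as.matrix(Sigma)
  M_O <- M_O %||% nrow(Sigma)
  ld <- tryCatch(log2_det_pd(Sigma),
                 error = function(e) stop("`Sigma` is not positive definite"))
  0.5 * (M_O * log2(2 * pi * exp(1)) + ld)
}

new_mi_estimate <- function(value, H_O, h_cond, estimator, n_samples,
                            se = NA_real_) {
  structure(list(value = value, H_O = H_O, h_cond = h_cond,
                 estimator = estimator, n_samples = n_samples,
                 se_realizations = se),
            class = "msinfo_mi")
}

#' @exportS3Method print msinfo_mi
print.msinfo_mi <- function(x, ...) {
  cat(sprintf("I(input; output) = %.4f bits  (H_O = %.4f, cond. = %.4f, %s, n = %d)\n",
              x$value, x$H_O, x$h_cond, x$estimator, x$n_samples))
  invisible(x)
}

#' Input-output mutual information with a closed-form conditional term
#'
#' For the direct and fast-processing architectures the conditional
#' output density is Gaussian with input-independent covariance, so
#' `I = H_O - h_{O|I}` needs only the output entropy estimated from the
#' pooled samples; `h_{O|I}` is [gaussian_conditional_entropy()] of the
#' output Lyapunov covariance. Only one-dimensional outputs are
#' supported by the numerical entropy estimate.
#'
#' @param batch an `msinfo_samples` batch from [sample_no_processing()]
#'   or [sample_fast_processing()].
#' @param Sigma_O stationary output covariance (or a
#'   [build_factorization()] object via `factorization`).
#' @param factorization optional factorization supplying `Sigma_O`.
#' @param estimator passed to [entropy_1d()].
#' @return An `msinfo_mi` estimate (bits). Point estimates are reported
#'   as computed and may be slightly negative at finite sample size.
#' @export
mi_fast <- function(batch, Sigma_O = NULL, factorization = NULL,
                    estimator = "knn") {
  stopifnot(inherits(batch, "msinfo_samples"))
  if (!batch$regime %in% c("no_processing", "fast_processing"))
    stop("batch regime must be no_processing or fast_processing; got ",
         batch$regime, " (use mi_slow)")
  if (is.null(Sigma_O)) {
    if (is.null(factorization))
      stop("supply `Sigma_O` or `factorization`")
    Sigma_O <- factorization$factors$O$Sigma
  }
  if (ncol(batch$x_O) != 1)
    stop("numerical entropy estimation supports one-dimensional outputs only")
  H_O <- entropy_1d(batch$x_O[, 1], estimator = estimator)
  h <- gaussian_conditional_entropy(Sigma_O)
  new_mi_estimate(H_O - h, H_O, h, estimator, nrow(batch$x_O))
}

#' @rdname mi_fast
#' @export
mi_direct_or_fast <- mi_fast

#' Input-output mutual information in the slow-processing regime
#'
#' With a slow processing unit the conditional output density is a
#' continuous Gaussian mixture and has no closed-form entropy, so
#' `H_{O|I}` is estimated directly from the nested batch: one
#' [entropy_1d()] per input block of `N_inner` outputs, averaged over
#' inputs (a plain Monte-Carlo average over input draws, since inputs
#' are drawn from their own stationary density with unit weights);
#' `H_O` comes from the pooled outputs. The standard error is the
#' jackknife-over-inputs error of the conditional term.
#'
#' @param batch a nested batch from [sample_slow_processing()].
#' @param estimator passed to [entropy_1d()].
#' @return An `msinfo_mi` estimate (bits).
#' @export
mi_slow <- function(batch, estimator = "knn") {
  stopifnot(inherits(batch, "msinfo_samples"))
  if (batch$regime != "slow_processing")
    stop("batch regime must be slow_processing")
  if (batch$N_inner < 100)
    stop("N_inner < 100: per-input entropy estimates would be too biased")
  if (ncol(batch$x_O) != 1)
    stop("numerical entropy estimation supports one-dimensional outputs only")
  xo <- batch$x_O[, 1]
  blocks <- matrix(xo, nrow = batch$N_inner)   # column i = input block i
  h_i <- apply(blocks, 2, entropy_1d, estimator = estimator)
  H_cond <- mean(h_i)
  se <- sd(h_i) / sqrt(batch$N_I)
  H_O <- entropy_1d(xo, estimator = estimator)
  new_mi_estimate(H_O - H_cond, H_O, H_cond, estimator, length(xo), se = se)
}

#' Sarle's bimodality coefficient
#'
#' `b = (s^2 + 1) / (kappa + q(n))` with the biased (1/n) sample skewness
#' `s`, excess kurtosis `kappa`, and the finite-sample correction
#' `q(n) = 3 (n-1)^2 / ((n-2)(n-3))`. A Gaussian sample gives
#' `b -> 1/3`; a symmetric two-point distribution gives `b -> 1`; larger
#' values indicate stronger bimodality.
#'
#' @param x numeric vector with more than 3 values and positive variance.
#' @return A list of class `msinfo_bimodality` with `b`, `s` (skewness),
#'   `kappa` (excess kurtosis), `q` and `n`.
#' @export
sarle_b <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n <= 3) stop("need more than 3 samples")
  mu <- mean(x)
  v <- mean(x^2) - mu^2
  if (v <= 0) stop("zero-variance sample")
  s <- mean((x - mu)^3) / v^1.5
  kappa <- mean((x - mu)^4) / v^2 - 3
  q <- 3 * (n - 1)^2 / ((n - 2) * (n - 3))
  structure(list(b = (s^2 + 1) / (kappa + q), s = s, kappa = kappa,
                 q = q, n = n),
            class = "msinfo_bimodality")
}

#' @exportS3Method print msinfo_bimodality
print.msinfo_bimodality <- function(x, ...) {
  cat(sprintf("Sarle b = %.4f (skewness %.3f, excess kurtosis %.3f, n = %d)\n",
              x$b, x$s, x$kappa, x$n))
  invisible(x)
}

#' Ensemble-averaged mutual information over random-matrix realizations
#'
#' Redraws every random interaction matrix per realization (rejecting
#' unstable intra-unit draws with an advanced seed), builds the
#' stationary factorization, samples it exactly and estimates the
#' input-output mutual information; reports the ensemble mean, standard
#' deviation and per-draw values, fully reproducible from one seed.
#'
#' @param params named list of arguments for [random_system()] (all but
#'   `scheme`, `regime`, `seed`).
#' @param n_realizations number of matrix realizations (>= 2).
#' @param regime `"no_processing"`, `"fast_processing"` or
#'   `"slow_processing"`.
#' @param scheme `"summation"` or `"integration"`.
#' @param N samples for the direct/fast estimators.
#' @param N_I,N_inner nesting for the slow estimator.
#' @param estimator entropy estimator.
#' @param seed master seed; realization `r` uses `derive_seed(seed, r)`.
#' @param bimodality also compute Sarle's coefficient of the pooled
#'   output per realization.
#' @param forced_seeds optional vector of explicit per-realization seeds
#'   (overrides the fan-out; mainly for reproducibility checks).
#' @return A list with `mean`, `sd`, `se`, `values`, and (if requested)
#'   `b_mean`, `b_sd`, `b_values`.
#' @export
ensemble_mi <- function(params, n_realizations, regime, scheme,
                        N = 4000, N_I = 250, N_inner = 150,
                        estimator = "knn", seed = 1, bimodality = FALSE,
                        forced_seeds = NULL) {
  stopifnot(n_realizations >= 2)
  vals <- numeric(n_realizations)
  bvals <- if (bimodality) numeric(n_realizations) else NULL
  rejections <- 0L
  for (r in seq_len(n_realizations)) {
    s_r <- if (!is.null(forced_seeds)) forced_seeds[r] else derive_seed(seed, r)
    sys <- do.call(random_system,
                   c(params, list(scheme = scheme, regime = regime,
                                  seed = s_r)))
    rejections <- rejections + attr(sys, "rejections")
    fact <- build_factorization(sys)
    if (regime == "slow_processing") {
      batch <- sample_slow_processing(sys, N_I = N_I, N_inner = N_inner,
                                      seed = derive_seed(s_r, 1L),
                                      factorization = fact)
      mi <- mi_slow(batch, estimator = estimator)
    } else {
      sampler <- if (regime == "fast_processing") sample_fast_processing
                 else sample_no_processing
      batch <- sampler(sys, N = N, seed = derive_seed(s_r, 1L),
                       factorization = fact)
      mi <- mi_fast(batch, factorization = fact, estimator = estimator)
    }
    vals[r] <- mi$value
    if (bimodality) bvals[r] <- sarle_b(batch$x_O[, 1])$b
  }
  if (rejections / (rejections + n_realizations) > 0.5)
    stop("more than half of the intra-unit draws were unstable; lower sigma")
  out <- list(mean = mean(vals), sd = sd(vals),
              se = sd(vals) / sqrt(n_realizations), values = vals,
              n_realizations = n_realizations, regime = regime,
              scheme = scheme)
  if (bimodality) {
    out$b_mean <- mean(bvals)
    out$b_sd <- sd(bvals)
    out$b_values <- bvals
  }
  out
}
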