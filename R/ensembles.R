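# Random interaction ensembles for intra- and inter-unit coupling matrices.

#' Draw an intra-unit interaction matrix from the Gaussian ensemble
#'
#' Off-diagonal entries are i.i.d. `N(0, (sigma/sqrt(M))^2)` (i.e. standard
#' deviation `sigma/sqrt(M)`) and every diagonal entry is exactly 1. With
#' this normalization the bulk spectrum approaches a disc of radius `sigma`
#' centred at 1, so the drift `-A x` is linearly stable for large `M`
#' whenever `sigma < 1`.
#'
#' @param M number of degrees of freedom (positive integer).
#' @param sigma ensemble heterogeneity (non-negative).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return An `M x M` numeric matrix with unit diagonal.
#' @seealso [check_stability()], [sample_inter_matrix()]
#' @export
sample_intra_matrix <- function(M, sigma, seed = NULL) {
  stopifnot(length(M) == 1, M >= 1, M == round(M))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop("`sigma` must be a single non-negative number")
  with_seed(seed, {
    A <- matrix(rnorm(M * M, mean = 0, sd = sigma / sqrt(M)), M, M)
    diag(A) <- 1
    A
  })
}

#' Draw an inter-unit interaction matrix with Bernoulli sparsity
#'
#' Each entry is present independently with probability `p_unit`; present
#' entries are `N(0, sigma^2)`. The per-row counts of present connections
#' are returned alongside the matrix: they are the normalization constants
#' of the sparse activation (each row of the activation divides by its own
#' connection count rather than by the full source dimension).
#'
#' @param M_target,M_source target and source unit dimensions.
#' @param sigma standard deviation of present entries (non-negative).
#' @param p_unit connection probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return A list with elements `W` (`M_target x M_source` matrix) and
#'   `counts` (integer vector of per-row connection counts). Rows with
#'   zero connections are allowed; downstream activations return 0 there.
#' @export
sample_inter_matrix <- function(M_target, M_source, sigma, p_unit = 1,
                                seed = NULL) {
  stopifnot(M_target >= 1, M_source >= 1, M_target == round(M_target),
            M_source == round(M_source))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop("`sigma` must be a single non-negative number")
  if (!is.numeric(p_unit) || length(p_unit) != 1 || p_unit < 0 || p_unit > 1)
    stop("`p_unit` must be a probability in [0, 1]")
  with_seed(seed, {
    W <- matrix(rnorm(M_target * M_source, sd = sigma), M_target, M_source)
    if (p_unit < 1) {
      mask <- matrix(rbinom(M_target * M_source, 1L, p_unit),
                     M_target, M_source)
      W <- W * mask
      counts <- as.integer(rowSums(mask))
    } else {
      counts <- rep(as.integer(M_source), M_target)
    }
    list(W = W, counts = counts)
  })
}

#' Draw an intra-unit matrix on a Barabasi-Albert topology
#'
#' The adjacency is an undirected preferential-attachment graph with
#' `attachment` edges per new node; each present (i, j) slot carries an
#' independent Gaussian weight of standard deviation `sigma/sqrt(M)` (the
#' same scaling as the dense ensemble, kept for comparability), the
#' diagonal is 1, and absent edges are exactly 0. The weights of the two
#' directions of an undirected edge are drawn independently.
#'
#' @param M number of nodes.
#' @param attachment edges added per new node (must be `< M`).
#' @param sigma weight heterogeneity (non-negative).
#' @param seed optional integer seed.
#' @return An `M x M` numeric matrix.
#' @export
sample_ba_intra_matrix <- function(M, attachment, sigma, seed = NULL) {
  stopifnot(M >= 1, M == round(M), attachment >= 1,
            attachment == round(attachment))
  if (attachment >= M)
    stop("`attachment` must be smaller than `M`")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop("`sigma` must be a single non-negative number")
  with_seed(seed, {
    g <- igraph::sample_pa(M, m = attachment, directed = FALSE)
    adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    A <- matrix(rnorm(M * M, sd = sigma / sqrt(M)), M, M) * (adj > 0)
    diag(A) <- 1
    A
  })
}

#' Check linear stability of an intra-unit coupling matrix
#'
#' The drift `-A x` is stable iff every eigenvalue of `A` has strictly
#' positive real part; the margin is the smallest real part.
#'
#' @param A square numeric matrix.
#' @return A list with `stable` (logical) and `margin` (min real part).
#' @export
check_stability <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("`A` must be a square matrix")
  margin <- min(Re(eigen(A, only.values = TRUE)$values))
  list(stable = margin > 0, margin = margin)
}

# Rejection-sampled stable intra-unit matrix: draws from the requested
# ensemble and advances the seed until check_stability passes. Stationary
# covariances only exist for stable drifts, so unstable draws are discarded
# (the number of rejections is recorded as an attribute).
sample_stable_intra <- function(M, sigma, seed = NULL, topology = "dense",
                                attachment = 2L, max_tries = 100L,
                                min_margin = 0) {
  tries <- 0L
  repeat {
    s <- if (is.null(seed)) NULL else as.integer(seed) + tries
    A <- switch(topology,
      dense = sample_intra_matrix(M, sigma, seed = s),
      barabasi_albert = sample_ba_intra_matrix(M, attachment, sigma, seed = s),
      stop("unknown topology: ", topology))
    if (check_stability(A)$margin > min_margin) {
      attr(A, "rejections") <- tries
      return(A)
    }
    tries <- tries + 1L
    if (tries >= max_tries)
      stop("no stable draw in ", max_tries, " tries (sigma = ", sigma,
           ", M = ", M, "); lower sigma")
    if (is.null(seed)) next
  }
}
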