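# Exact sampling from the stationary factorized distributions.

new_sample_batch <- function(regime, x_I, x_O, x_P = NULL, seed = NULL,
                             N = nrow(x_I), N_I = NULL, N_inner = NULL) {
  if (any(!is.finite(x_I)) || any(!is.finite(x_O)) ||
      (!is.null(x_P) && any(!is.finite(x_P))))
    stop("non-finite values in sample batch")
  structure(list(regime = regime, x_I = x_I, x_P = x_P, x_O = x_O,
                 seed = seed, N = N, N_I = N_I, N_inner = N_inner),
            class = "msinfo_samples")
}

#' @exportS3Method print msinfo_samples
print.msinfo_samples <- function(x, ...) {
  cat("Exact stationary samples (", x$regime, "): ", sep = "")
  if (x$regime == "slow_processing")
    cat(x$N_I, " inputs x ", x$N_inner, " inner draws\n", sep = "")
  else cat(x$N, " draws\n", sep = "")
  invisible(x)
}

#' Exact stationary samples of the direct input-output system
#'
#' Draws `x_I ~ N(0, Sigma_I)` and, per draw, `x_O` from the conditional
#' Gaussian with mean `g_OI A_O^{-1} phi(x_I)` and the output Lyapunov
#' covariance.
#'
#' @param system an `msinfo_system` in the `no_processing` regime (or a
#'   prebuilt [build_factorization()] via `factorization`).
#' @param N number of joint samples.
#' @param seed integer seed.
#' @param factorization optional prebuilt factorization (avoids repeated
#'   Lyapunov solves inside ensemble loops).
#' @return An `msinfo_samples` batch with `x_I` (`N x M_I`) and `x_O`
#'   (`N x M_O`).
#' @export
sample_no_processing <- function(system, N, seed = NULL,
                                 factorization = NULL) {
  fact <- factorization %||% build_factorization(system)
  if (fact$regime != "no_processing")
    stop("system/factorization is not in the no_processing regime")
  with_seed(seed, {
    x_I <- rmvn_chol(N, fact$factors$I$R)
    m_O <- fact$factors$O$mean_map(x_I)
    x_O <- m_O + rmvn_chol(N, fact$factors$O$R)
    new_sample_batch("no_processing", x_I, x_O, seed = seed, N = N)
  })
}

#' Exact stationary samples with a fast processing unit
#'
#' Implements the fast-processing recipe: draw the input from its
#' stationary Gaussian, evaluate the effective conditional output mean
#' (which integrates out the fast processing fluctuations through the
#' smoothed activation), and draw the output around it with the output
#' Lyapunov covariance. Processing states can optionally be drawn from
#' `N(m_PI(x_I), Sigma_P)` for diagnostics (off by default to bound
#' memory).
#'
#' @inheritParams sample_no_processing
#' @param keep_P also draw and retain processing states.
#' @return An `msinfo_samples` batch.
#' @export
sample_fast_processing <- function(system, N, seed = NULL, keep_P = FALSE,
                                   factorization = NULL) {
  fact <- factorization %||% build_factorization(system)
  if (fact$regime != "fast_processing")
    stop("system/factorization is not in the fast_processing regime")
  with_seed(seed, {
    x_I <- rmvn_chol(N, fact$factors$I$R)
    m_O <- fact$factors$O$mean_map(x_I)
    x_O <- m_O + rmvn_chol(N, fact$factors$O$R)
    x_P <- NULL
    if (keep_P) {
      m_P <- fact$factors$P$mean_map(x_I)
      x_P <- m_P + rmvn_chol(N, fact$factors$P$R)
    }
    new_sample_batch("fast_processing", x_I, x_O, x_P = x_P,
                     seed = seed, N = N)
  })
}

#' Exact nested stationary samples with a slow processing unit
#'
#' The slow-processing factorization is the Markov chain
#' `I -> P -> O`, so the conditional output entropy must be estimated
#' numerically: for each of `N_I` input draws, `N_inner` processing
#' states are drawn from `N(m_PI(x_I), Sigma_P)` and one output per
#' processing state from `N(m_OP(x_P), Sigma_O)`. The nesting structure
#' is retained (rows of `x_O` are grouped in `N_I` blocks of `N_inner`)
#' for conditional-entropy estimation by [mi_slow()].
#'
#' @inheritParams sample_no_processing
#' @param N_I number of outer input draws.
#' @param N_inner inner (processing/output) draws per input.
#' @return An `msinfo_samples` batch; `x_O` has `N_I * N_inner` rows in
#'   input-major order.
#' @export
sample_slow_processing <- function(system, N_I = 2000, N_inner = 2000,
                                   seed = NULL, factorization = NULL,
                                   keep_P = FALSE) {
  fact <- factorization %||% build_factorization(system)
  if (fact$regime != "slow_processing")
    stop("system/factorization is not in the slow_processing regime")
  with_seed(seed, {
    x_I <- rmvn_chol(N_I, fact$factors$I$R)
    m_P <- fact$factors$P$mean_map(x_I)             # N_I x M_P
    m_P_rep <- m_P[rep(seq_len(N_I), each = N_inner), , drop = FALSE]
    x_P <- m_P_rep + rmvn_chol(N_I * N_inner, fact$factors$P$R)
    m_O <- fact$factors$O$mean_map(x_P)
    x_O <- m_O + rmvn_chol(N_I * N_inner, fact$factors$O$R)
    new_sample_batch("slow_processing", x_I, x_O,
                     x_P = if (keep_P) x_P else NULL,
                     seed = seed, N = N_I * N_inner,
                     N_I = N_I, N_inner = N_inner)
  })
}
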