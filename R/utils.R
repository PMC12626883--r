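# Internal numerical and random-number helpers.

#' Derive a reproducible child seed from a master seed
#'
#' Counter-based fan-out: grid points, realizations and regimes get
#' independent, order-insensitive streams from one master seed. Uses a
#' 32-bit mixing hash, so the result is always a valid R seed.
#'
#' @param master integer master seed.
#' @param ... integer counters (realization index, grid index, ...).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(as.integer(master), as.integer(c(...)))
  # multiplicative congruential mixing in double arithmetic: every product
  # stays below 2^48, i.e. exactly representable
  h <- 104729
  for (k in idx) {
    h <- (h * 69069 + (k %% 2147483647) + 1) %% 2147483647
    h <- (h * 69069 + 12345) %% 2147483647
  }
  as.integer(h)
}

# Run code under a local RNG state: seeds if `seed` is non-NULL and always
# restores the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# N draws from N(0, Sigma) given an upper-triangular Cholesky factor R
# (Sigma = R'R), returned as an N x M matrix. The factor is computed once
# per system and reused across samples.
rmvn_chol <- function(n, R) {
  m <- ncol(R)
  matrix(rnorm(n * m), n, m) %*% R
}

# Scaled complementary error function erfcx(z) = exp(z^2) erfc(z) for
# z >= 0. pracma::erfcx overflows to NaN above z ~ 27; beyond 25 we switch
# to the asymptotic expansion 1/(z sqrt(pi)) sum_k (-1)^k (2k-1)!!/(2z^2)^k,
# whose truncation error at z = 25 is far below machine precision.
erfcx_pos <- function(z) {
  out <- numeric(length(z))
  small <- z < 25
  if (any(small)) out[small] <- pracma::erfcx(z[small])
  if (any(!small)) {
    zz <- z[!small]
    inv2z2 <- 1 / (2 * zz^2)
    term <- rep(1, length(zz))
    s <- term
    for (k in 1:12) {
      term <- -term * (2 * k - 1) * inv2z2
      s <- s + term
    }
    out[!small] <- s / (zz * sqrt(pi))
  }
  out
}

# log2 determinant of a positive-definite matrix via Cholesky.
log2_det_pd <- function(S) {
  2 * sum(log2(diag(chol(S))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
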