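# Internal numeric helpers shared across modules.

# Log density of rows of X under N(mu, Sigma), via Cholesky.
.log_dmvnorm <- function(X, mu, Sigma) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  p <- ncol(X)
  L <- chol(Sigma)
  z <- backsolve(L, t(X) - mu, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(L))) - 0.5 * p * log(2 * pi)
}

# Log density of rows of X under multivariate-t with df nu, location mu,
# scale matrix Sigma.
.log_dmvt <- function(X, mu, Sigma, nu) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  p <- ncol(X)
  L <- chol(Sigma)
  z <- backsolve(L, t(X) - mu, transpose = TRUE)
  d2 <- colSums(z^2)
  lgamma((nu + p) / 2) - lgamma(nu / 2) - 0.5 * p * log(nu * pi) -
    sum(log(diag(L))) - 0.5 * (nu + p) * log1p(d2 / nu)
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Symmetrise and add a small ridge so chol() succeeds.
.ridge_spd <- function(S, rel = 1e-6) {
  S <- (S + t(S)) / 2
  S + diag(rel * sum(diag(S)) / nrow(S), nrow(S))
}

# Ledoit-Wolf style shrinkage of a sample covariance towards its diagonal,
# with the shrinkage intensity estimated from the data (Schafer-Strimmer).
.shrink_cov_diag <- function(X) {
  n <- nrow(X)
  S <- stats::cov(X)
  if (n < 3L) {
    lambda <- 1
  } else {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    p <- ncol(X)
    # W2[i,j] = sum_k (x_ki x_kj)^2 ; used for Var-hat of each covariance entry
    W1 <- crossprod(Xc) / n                 # = (n-1)/n * S
    W2 <- crossprod(Xc^2)
    varS <- n / (n - 1)^3 * (W2 - n * W1^2)
    off <- upper.tri(S)
    num <- sum(varS[off])
    den <- sum(S[off]^2)
    lambda <- if (den > 0) min(1, max(0, num / den)) else 1
  }
  Sh <- (1 - lambda) * S + lambda * diag(diag(S), ncol(X))
  list(cov = .ridge_spd(Sh), lambda = lambda)
}
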