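# Independent oracles: deliberately naive implementations (explicit
# inverses, brute-force sums, enumeration) kept separate from the package's
# computational paths.

# Restricted log-likelihood via the error-contrast representation: C is an
# orthonormal basis of the null space of X', and the REML likelihood is the
# Gaussian log-density of C'y under N(0, C'VC). Differs from the package's
# -1/2[ln|V| + ln|X'V^-1X| + y'Py] by the constant
# -1/2[(n-q) ln(2 pi) - ln|X'X|].
oracle_contrast_loglik <- function(V, X, y) {
  X <- as.matrix(X)
  n <- nrow(X); q <- ncol(X)
  Cb <- qr.Q(qr(X), complete = TRUE)[, (q + 1):n, drop = FALSE]
  S <- crossprod(Cb, V %*% Cb)
  z <- drop(crossprod(Cb, y))
  as.numeric(-0.5 * ((n - q) * log(2 * pi) + determinant(S)$modulus +
                       z %*% solve(S, z)))
}

oracle_contrast_constant <- function(X) {
  X <- as.matrix(X)
  as.numeric(-0.5 * ((nrow(X) - ncol(X)) * log(2 * pi) -
                       determinant(crossprod(X))$modulus))
}

# Naive projection matrix with explicit inverses
oracle_projection <- function(V, X) {
  Vi <- solve(V)
  Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
}

# Independent EM-REML: fixed-point updates with explicit inverses, run to a
# tight tolerance. Variance components only (no covariances).
oracle_em_reml <- function(y, K_list, X = NULL, max_iter = 5000, tol = 1e-12) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  dV <- c(K_list, list(diag(n)))
  q <- length(dV)
  theta <- rep(var(y) / q, q)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    V <- Reduce(`+`, Map(`*`, dV, theta))
    P <- oracle_projection(V, X)
    Py <- P %*% y
    theta_new <- vapply(seq_len(q), function(r) {
      theta[r] + theta[r]^2 *
        (drop(t(Py) %*% dV[[r]] %*% Py) - sum(P * dV[[r]])) / n
    }, 0)
    theta_new <- pmax(theta_new, 1e-10)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol) break
  }
  theta
}

# Conditional mean of the test block under the joint Gaussian implied by the
# parameters: full V assembled naively, then standard conditioning.
oracle_blup <- function(theta_var, theta_cov, resid, K_list, B_list, y,
                        train, test, X) {
  n <- length(y)
  Vfull <- diag(resid, n)
  for (i in seq_along(K_list)) Vfull <- Vfull + K_list[[i]] * theta_var[i]
  for (j in seq_along(B_list)) Vfull <- Vfull + B_list[[j]] * theta_cov[j]
  Cfull <- Vfull - diag(resid, n)  # signal covariance
  Xt <- X[train, , drop = FALSE]
  Vt <- Vfull[train, train]
  b <- solve(t(Xt) %*% solve(Vt, Xt), t(Xt) %*% solve(Vt, y[train]))
  drop(Cfull[test, train] %*% solve(Vt, y[train] - Xt %*% b))
}

# Monte-Carlo delta method: sample parameters from N(theta_hat, C), push
# through fn, report the SD.
oracle_mc_delta <- function(fn, theta_hat, C, n_draws = 50000, seed = 1) {
  set.seed(seed)
  R <- chol(C)
  Z <- matrix(rnorm(n_draws * length(theta_hat)), n_draws)
  draws <- sweep(Z %*% R, 2, theta_hat, "+")
  vals <- apply(draws, 1, fn)
  sd(vals[is.finite(vals)])
}

# Exact dosage correlation between adjacent SNPs at f = 0.5 under the
# latent AR(1) threshold model: allele indicators are Bernoulli(1/2) with
# P(both) = 1/4 + asin(rho)/(2*pi), so corr = (2/pi) asin(rho).
oracle_dosage_corr_half <- function(rho) 2 * asin(rho) / pi

# Sample skewness
sample_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
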