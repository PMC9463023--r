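# Independent numerical oracles used by the test suite only.

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen-decomposition of the
# Jacobi matrix); exact for polynomials of degree 2n-1.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Exact (to quadrature accuracy) marginal log-likelihood of the random-
# intercept binomial GLMM by n-node Gauss-Hermite integration per group.
ghq_loglik <- function(beta, sigma, y, m, X, group, nodes = 200) {
  gh <- gauss_hermite(nodes)
  eta0 <- as.vector(X %*% beta)
  ll <- sum(lchoose(m, y))
  for (idx in split(seq_along(y), group)) {
    u <- sqrt(2) * sigma * gh$nodes
    lg <- vapply(u, function(uu)
      sum(y[idx] * (eta0[idx] + uu) - m[idx] * log1p(exp(eta0[idx] + uu))), 0)
    mx <- max(lg)
    ll <- ll + mx + log(sum(gh$weights / sqrt(pi) * exp(lg - mx)))
  }
  ll
}

# fixed one-factor aggregated-binomial dataset (n = 20, 5 groups) for the
# likelihood-oracle checks
quadrature_fixture <- function() {
  set.seed(42)
  n <- 20
  g <- rep(1:5, each = 4)
  x <- round(rnorm(n), 3)
  m <- rep(20L, n)
  eta <- 0.3 + 0.6 * x + rep(round(rnorm(5, 0, 0.1), 3), each = 4)
  y <- rbinom(n, m, plogis(eta))
  list(y = y, m = m, X = cbind(1, x), x = x, group = g)
}

# closed-form least squares (normal equations)
ols_oracle <- function(X, y) as.vector(solve(crossprod(X), crossprod(X, y)))

# logistic ML by Newton-Raphson from scratch
logistic_ml_oracle <- function(X, y, m = rep(1, length(y)), tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in 1:100) {
    p <- plogis(as.vector(X %*% beta))
    W <- m * p * (1 - p)
    score <- crossprod(X, y - m * p)
    H <- crossprod(X * W, X)
    step <- solve(H, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# one-sample KS statistic by direct enumeration of the step-function supremum
ks_enumeration_oracle <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(pmax(abs(seq_len(n) / n - Fx), abs(Fx - (seq_len(n) - 1) / n)))
}
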