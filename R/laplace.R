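# First-order Laplace evaluation of the marginal log-likelihood of a
# random-intercept binomial (logit) GLMM at fixed parameter values.  This is
# the approximation underlying the binomial mixed-model fits; having it as a
# standalone evaluator lets the test suite compare it against high-order
# numerical quadrature.

#' Laplace-approximated marginal log-likelihood of a binomial GLMM
#'
#' Model: y_ij ~ Binomial(m_ij, plogis(x_ij' beta + u_j)), u_j ~ N(0, sigma^2),
#' one grouping factor.  For each group the random-intercept mode is found by
#' Newton iteration and the one-dimensional integral is replaced by its
#' Laplace approximation.  Binomial-coefficient constants are included, so
#' the value is comparable to exact quadrature of the same likelihood.
#'
#' @param beta fixed-effect coefficient vector (matching columns of X).
#' @param sigma random-intercept SD (>= 0; 0 collapses to plain binomial).
#' @param y numeric vector of successes.
#' @param m numeric vector of trials (1 for Bernoulli).
#' @param X design matrix (rows = observations).
#' @param group grouping factor/vector, one level per cluster.
#' @return the marginal log-likelihood (scalar).
#' @export
laplace_loglik <- function(beta, sigma, y, m, X, group) {
  stopifnot(length(y) == length(m), nrow(X) == length(y),
            ncol(X) == length(beta), sigma >= 0)
  eta0 <- as.vector(X %*% beta)
  const <- sum(lchoose(m, y))
  if (sigma == 0) {
    return(const + sum(y * eta0 - m * log1p(exp(eta0))))
  }
  groups <- split(seq_along(y), group)
  ll <- const
  for (idx in groups) {
    e0 <- eta0[idx]; yj <- y[idx]; mj <- m[idx]
    u <- 0
    for (it in 1:50) {
      p <- plogis(e0 + u)
      g <- sum(yj - mj * p) - u / sigma^2          # d/du log integrand
      h <- -sum(mj * p * (1 - p)) - 1 / sigma^2    # second derivative
      step <- g / h
      u <- u - step
      if (abs(step) < 1e-12) break
    }
    p <- plogis(e0 + u)
    h <- -sum(mj * p * (1 - p)) - 1 / sigma^2
    logint <- sum(yj * (e0 + u) - mj * log1p(exp(e0 + u))) +
      dnorm(u, 0, sigma, log = TRUE)
    ll <- ll + logint + 0.5 * log(2 * pi) - 0.5 * log(-h)
  }
  ll
}
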