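# Metropolis-within-Gibbs samplers for the path-model regressions.
#
# Every edge regression has the form  y_i = alpha + beta * x_i + eps_site(i)
# with minimally informative priors: alpha, beta ~ N(0, precision 0.001),
# Gamma(0.001, 0.001) on the random-effect precision (and, for Gaussian
# responses, on the residual precision).  Gaussian edges are fully conjugate
# and use plain Gibbs draws; the Bernoulli-logit endpoint uses adaptive
# random-walk Metropolis for (alpha, beta) jointly and for the site effects,
# with proposal scales tuned during burn-in only.

#' Priors of the path-model regressions
#'
#' @param coef_prec prior precision of intercepts and path coefficients
#'   (normal, mean 0).
#' @param re_prec_shape,re_prec_rate gamma prior on the site random-effect
#'   precision.
#' @param resid_prec_shape,resid_prec_rate gamma prior on the Gaussian
#'   residual precision.
#' @return list of class \code{cw_priors}.
#' @export
prior_spec <- function(coef_prec = 0.001, re_prec_shape = 0.001,
                       re_prec_rate = 0.001, resid_prec_shape = 0.001,
                       resid_prec_rate = 0.001) {
  stopifnot(coef_prec > 0, re_prec_shape > 0, re_prec_rate > 0,
            resid_prec_shape > 0, resid_prec_rate > 0)
  structure(list(coef_prec = coef_prec, re_prec_shape = re_prec_shape,
                 re_prec_rate = re_prec_rate,
                 resid_prec_shape = resid_prec_shape,
                 resid_prec_rate = resid_prec_rate), class = "cw_priors")
}

#' MCMC schedule
#'
#' The canonical schedule is 3 chains of 200,000 iterations with a burn-in
#' of 15,000 and thinning interval 3.  The \code{"fast"} profile (3 x
#' 20,000, burn-in 2,000, thin 3) is a reduced schedule for routine runs and
#' is marked non-canonical in outputs.
#'
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param iterations iterations per chain (including burn-in).
#' @param burn_in discarded initial iterations.
#' @param thin thinning interval (>= 1).
#' @param seed integer root seed.
#' @param profile \code{NULL}, \code{"canonical"} or \code{"fast"};
#'   overrides the schedule numbers.
#' @return list of class \code{cw_mcmc_config}.
#' @export
mcmc_config <- function(chains = 3L, iterations = 200000L, burn_in = 15000L,
                        thin = 3L, seed = 1L, profile = NULL) {
  if (!is.null(profile)) {
    if (profile == "canonical") {
      iterations <- 200000L; burn_in <- 15000L; thin <- 3L
    } else if (profile == "fast") {
      iterations <- 20000L; burn_in <- 2000L; thin <- 3L
    } else stopf("unknown MCMC profile '%s'", profile)
  }
  stopifnot(burn_in < iterations, thin >= 1, chains >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 canonical = iterations >= 200000L),
            class = "cw_mcmc_config")
}

# kept iteration indices for a schedule
kept_iterations <- function(config) {
  seq.int(config$burn_in + config$thin, config$iterations, by = config$thin)
}

# Gaussian edge: fully conjugate Gibbs.  Returns kept draws per chain.
# tau_fixed fixes the residual precision (used by closed-form checks);
# site = NULL drops the random effect.
sample_gaussian_edge <- function(y, x, site, prior, config, chain_seed,
                                 tau_fixed = NULL) {
  n <- length(y)
  set.seed(chain_seed)
  keep <- kept_iterations(config)
  n_keep <- length(keep)
  out <- list(alpha = numeric(n_keep), beta = numeric(n_keep),
              sd_site = numeric(n_keep), sigma = numeric(n_keep))
  has_re <- !is.null(site) && n > 0
  if (has_re) {
    site_f <- factor(site)
    J <- nlevels(site_f)
    si <- as.integer(site_f)
    nj <- tabulate(si, J)
  }
  a <- 0; b <- 0
  tau <- if (is.null(tau_fixed)) 1 else tau_fixed
  tau_site <- 1
  eps <- if (has_re) numeric(J) else NULL
  if (n > 0) {
    XtX <- matrix(c(n, sum(x), sum(x), sum(x * x)), 2)
  }
  c0 <- prior$coef_prec
  ki <- 1L
  for (it in seq_len(config$iterations)) {
    if (n == 0) {
      ab <- rnorm(2, 0, sqrt(1 / c0)); a <- ab[1]; b <- ab[2]
      if (is.null(tau_fixed))
        tau <- rgamma(1, prior$resid_prec_shape, prior$resid_prec_rate)
      tau_site <- rgamma(1, prior$re_prec_shape, prior$re_prec_rate)
    } else {
      r1 <- y - (if (has_re) eps[si] else 0)
      A <- tau * XtX + diag(c0, 2)
      ch <- chol(A)
      mu <- backsolve(ch, forwardsolve(t(ch), tau * c(sum(r1), sum(x * r1))))
      ab <- mu + backsolve(ch, rnorm(2))
      a <- ab[1]; b <- ab[2]
      if (has_re) {
        r2 <- y - a - b * x
        prec_j <- tau * nj + tau_site
        mean_j <- tau * as.vector(rowsum(r2, si)) / prec_j
        eps <- rnorm(J, mean_j, 1 / sqrt(prec_j))
        tau_site <- rgamma(1, prior$re_prec_shape + J / 2,
                           prior$re_prec_rate + sum(eps^2) / 2)
      }
      if (is.null(tau_fixed)) {
        resid <- y - a - b * x - (if (has_re) eps[si] else 0)
        tau <- rgamma(1, prior$resid_prec_shape + n / 2,
                      prior$resid_prec_rate + sum(resid^2) / 2)
      }
    }
    if (ki <= n_keep && it == keep[ki]) {
      out$alpha[ki] <- a; out$beta[ki] <- b
      out$sd_site[ki] <- if (has_re) 1 / sqrt(tau_site) else NA_real_
      out$sigma[ki] <- 1 / sqrt(tau)
      ki <- ki + 1L
    }
  }
  out
}

# Bernoulli-logit edge: adaptive random-walk Metropolis within Gibbs.
sample_bernoulli_edge <- function(y, x, site, prior, config, chain_seed) {
  n <- length(y)
  set.seed(chain_seed)
  keep <- kept_iterations(config)
  n_keep <- length(keep)
  out <- list(alpha = numeric(n_keep), beta = numeric(n_keep),
              sd_site = numeric(n_keep))
  has_re <- !is.null(site) && n > 0
  c0 <- prior$coef_prec
  if (n == 0) {
    # no data: the posterior is the prior; sample it directly
    out$alpha <- rnorm(n_keep, 0, sqrt(1 / c0))
    out$beta <- rnorm(n_keep, 0, sqrt(1 / c0))
    out$sd_site <- 1 / sqrt(rgamma(n_keep, prior$re_prec_shape,
                                   prior$re_prec_rate))
    return(out)
  }
  if (has_re) {
    site_f <- factor(site)
    J <- nlevels(site_f)
    si <- as.integer(site_f)
    xbar_j <- as.vector(rowsum(x, si)) / tabulate(si, J)
  }
  # initialize at the plain logistic fit; its vcov seeds the joint proposal
  init <- tryCatch(glm(y ~ x, family = binomial), error = function(e) NULL)
  if (!is.null(init) && all(is.finite(coef(init))) &&
      all(is.finite(vcov(init)))) {
    ab <- unname(coef(init))
    prop_chol <- chol(vcov(init) * (2.38^2 / 2) + diag(1e-8, 2))
  } else {
    ab <- c(0, 0)
    prop_chol <- chol(diag(0.25, 2))
  }
  eps <- if (has_re) numeric(J) else NULL
  tau_site <- 1
  log_scale <- 0; log_scale_eps <- log(0.5)
  log_scale_shift <- log(0.5); log_scale_slope <- log(0.5)
  log_scale_scl <- log(0.3)
  n_acc <- c(ab = 0, eps = 0, shift = 0, slope = 0, scale = 0)
  eta_re <- if (has_re) eps[si] else 0
  loglik_ab <- function(a, b) {
    eta <- a + b * x + eta_re
    sum(y * eta - log1p(exp(eta)))
  }
  cur_ll <- loglik_ab(ab[1], ab[2])
  if (!is.finite(cur_ll)) stopf("divergent chain: non-finite log-posterior at init")
  # burn-in history for Haario-style covariance adaptation of (alpha, beta)
  hist_ab <- matrix(0, config$burn_in, 2)
  ki <- 1L
  for (it in seq_len(config$iterations)) {
    adapting <- it <= config$burn_in
    ## joint (alpha, beta) random-walk update
    prop <- ab + exp(log_scale) * as.vector(t(prop_chol) %*% rnorm(2))
    prop_ll <- loglik_ab(prop[1], prop[2])
    log_r <- (prop_ll - cur_ll) +
      (-c0 / 2 * sum(prop^2)) - (-c0 / 2 * sum(ab^2))
    acc <- is.finite(log_r) && log(runif(1)) < log_r
    if (acc) { ab <- prop; cur_ll <- prop_ll; n_acc["ab"] <- n_acc["ab"] + 1 }
    if (adapting) {
      # Robbins-Monro step toward acceptance rate 0.3 (burn-in only)
      log_scale <- log_scale + ((if (acc) 1 else 0) - 0.3) / sqrt(it)
      log_scale <- max(-4, min(3, log_scale))
      if (it <= nrow(hist_ab)) hist_ab[it, ] <- ab
      if (it >= 500 && it %% 250 == 0) {
        emp <- stats::cov(hist_ab[max(1, it - 2000):it, , drop = FALSE])
        if (all(is.finite(emp)))
          prop_chol <- chol(emp * (2.38^2 / 2) + diag(1e-8, 2))
      }
    }
    ## site effects: simultaneous independent random-walk updates
    if (has_re) {
      prop_eps <- eps + exp(log_scale_eps) * rnorm(J)
      eta_base <- ab[1] + ab[2] * x
      ll_cur_i <- y * (eta_base + eps[si]) - log1p(exp(eta_base + eps[si]))
      ll_prop_i <- y * (eta_base + prop_eps[si]) -
        log1p(exp(eta_base + prop_eps[si]))
      d_j <- as.vector(rowsum(ll_prop_i - ll_cur_i, si)) -
        tau_site / 2 * (prop_eps^2 - eps^2)
      acc_j <- log(runif(J)) < d_j
      eps[acc_j] <- prop_eps[acc_j]
      n_acc["eps"] <- n_acc["eps"] + mean(acc_j)
      eta_re <- eps[si]
      cur_ll <- loglik_ab(ab[1], ab[2])
      if (adapting) {
        rate <- mean(acc_j)
        log_scale_eps <- max(-4, min(2, log_scale_eps +
                                       (rate - 0.44) / sqrt(it) * 2))
      }
      ## translation move: shift delta from the site effects into the
      ## intercept; the likelihood is invariant, acceptance is prior-only.
      ## Breaks the alpha vs random-intercept confounding.
      delta <- exp(log_scale_shift) * rnorm(1)
      log_r <- -c0 / 2 * ((ab[1] + delta)^2 - ab[1]^2) -
        tau_site / 2 * (sum((eps - delta)^2) - sum(eps^2))
      acc_s <- is.finite(log_r) && log(runif(1)) < log_r
      if (acc_s) {
        ab[1] <- ab[1] + delta
        eps <- eps - delta
        eta_re <- eps[si]
        n_acc["shift"] <- n_acc["shift"] + 1
      }
      if (adapting)
        log_scale_shift <- max(-4, min(2, log_scale_shift +
                                         ((if (acc_s) 1 else 0) - 0.35) /
                                           sqrt(it)))
      ## slope-shift move: beta + delta compensated through the site effects
      ## by each site's mean predictor value; near likelihood-invariant, so
      ## it crosses the beta vs random-effect ridge efficiently.
      delta <- exp(log_scale_slope) * rnorm(1)
      beta_p <- ab[2] + delta
      eps_p <- eps - delta * xbar_j
      eta_p <- ab[1] + beta_p * x + eps_p[si]
      ll_p <- sum(y * eta_p - log1p(exp(eta_p)))
      log_r <- (ll_p - cur_ll) -
        c0 / 2 * (beta_p^2 - ab[2]^2) -
        tau_site / 2 * (sum(eps_p^2) - sum(eps^2))
      acc_b <- is.finite(log_r) && log(runif(1)) < log_r
      if (acc_b) {
        ab[2] <- beta_p; eps <- eps_p
        eta_re <- eps[si]
        cur_ll <- ll_p
        n_acc["slope"] <- n_acc["slope"] + 1
      }
      if (adapting)
        log_scale_slope <- max(-4, min(2, log_scale_slope +
                                         ((if (acc_b) 1 else 0) - 0.35) /
                                           sqrt(it)))
      tau_site <- rgamma(1, prior$re_prec_shape + J / 2,
                         prior$re_prec_rate + sum(eps^2) / 2)
      ## funnel scale move: jointly rescale the site effects and their
      ## precision (eps' = s*eps, tau' = tau/s^2).  The Gaussian prior terms
      ## cancel against the Jacobian, so acceptance is the likelihood ratio
      ## plus the (nearly flat) gamma prior on the precision.
      ls <- exp(log_scale_scl) * rnorm(1)
      s <- exp(ls)
      eps_p <- s * eps
      tau_p <- tau_site / s^2
      eta_p <- ab[1] + ab[2] * x + eps_p[si]
      ll_p <- sum(y * eta_p - log1p(exp(eta_p)))
      log_r <- (ll_p - cur_ll) +
        prior$re_prec_shape * (log(tau_p) - log(tau_site)) -
        prior$re_prec_rate * (tau_p - tau_site)
      acc_f <- is.finite(log_r) && log(runif(1)) < log_r
      if (acc_f) {
        eps <- eps_p; tau_site <- tau_p
        eta_re <- eps[si]
        cur_ll <- ll_p
        n_acc["scale"] <- n_acc["scale"] + 1
      }
      if (adapting)
        log_scale_scl <- max(-4, min(2, log_scale_scl +
                                       ((if (acc_f) 1 else 0) - 0.35) /
                                         sqrt(it)))
    }
    if (!is.finite(cur_ll))
      stopf("divergent chain: non-finite log-posterior at iteration %d", it)
    if (ki <= n_keep && it == keep[ki]) {
      out$alpha[ki] <- ab[1]; out$beta[ki] <- ab[2]
      out$sd_site[ki] <- if (has_re) 1 / sqrt(tau_site) else NA_real_
      ki <- ki + 1L
    }
  }
  out$accept_rates <- n_acc / config$iterations
  out
}
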