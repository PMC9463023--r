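tiny_cfg <- function(seed = 1, chains = 2)
  mcmc_config(chains = chains, iterations = 3000, burn_in = 500, thin = 2,
              seed = seed)

# small standardized analysis table with known edge effects
make_path_data <- function(n_site = 20, per_site = 3, b_ret = 0.5,
                           b_succ = 0.4, seed = 1) {
  set.seed(seed)
  n <- n_site * per_site
  site <- rep(sprintf("S%02d", seq_len(n_site)), each = per_site)
  q <- rnorm(n)
  ret <- b_ret * q + rnorm(n, 0, sqrt(max(0, 1 - b_ret^2)))
  succ <- rbinom(n, 1, plogis(0.4 + b_succ * ret))
  z <- function(v) (v - mean(v)) / sd(v)
  data.frame(site_id = site, quality_z = z(q), return_z = z(ret),
             freq_z = z(rnorm(n)), laydate_z = z(rnorm(n)), success = succ,
             stringsAsFactors = FALSE)
}

test_that("the five fixed pathways are built as specified", {
  pws <- build_pathways()
  expect_length(pws, 5)
  expect_equal(pws[[1]]$chain, c("quality_z", "success"))
  expect_length(pws[[1]]$edges, 1)
  expect_equal(pws[[5]]$chain,
               c("quality_z", "return_z", "freq_z", "laydate_z", "success"))
  for (p in pws) {
    expect_equal(p$chain[1], "quality_z")
    expect_equal(p$chain[length(p$chain)], "success")
    expect_equal(p$edges[[length(p$edges)]]$family, "bernoulli")
  }
})

test_that("Gelman-Rubin statistic separates converged from divergent chains", {
  set.seed(4)
  x <- rnorm(5000)
  expect_equal(gelman_rubin(cbind(x, x)), 1)
  two <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(gelman_rubin(two), 1.05)
  div <- cbind(rnorm(1000), rnorm(1000, 10))
  expect_gt(gelman_rubin(div), 1.1)
  expect_error(gelman_rubin(matrix(x, ncol = 1)), ">= 2 chains")
})

test_that("effective sample size tracks the autocorrelation time", {
  set.seed(8)
  iid <- matrix(rnorm(20000), ncol = 2)
  expect_equal(effective_sample_size(iid), 20000, tolerance = 0.1)
  # AR(1) with rho = 0.9: ESS ~ N (1-rho)/(1+rho)
  rho <- 0.9
  n <- 40000
  ar <- as.vector(arima.sim(list(ar = rho), n))
  expect_equal(effective_sample_size(matrix(ar, ncol = 1)),
               n * (1 - rho) / (1 + rho), tolerance = 0.25)
  # thinning an autocorrelated chain raises ESS per retained draw
  thin <- ar[seq(1, n, by = 3)]
  ess_full <- effective_sample_size(matrix(ar, ncol = 1)) / n
  ess_thin <- effective_sample_size(matrix(thin, ncol = 1)) / length(thin)
  expect_gt(ess_thin, ess_full)
  expect_error(effective_sample_size(matrix(1, 100, 1)), "constant chain")
})

test_that("conjugate Gaussian edge matches the closed-form posterior", {
  set.seed(12)
  n <- 60
  x <- rnorm(n)
  y <- 0.3 + 0.6 * x + rnorm(n)
  cfg <- mcmc_config(chains = 1, iterations = 8000, burn_in = 1000, thin = 1,
                     seed = 2)
  dr <- colonywatch:::sample_gaussian_edge(y, x, site = NULL, prior_spec(),
                                           cfg, chain_seed = 42,
                                           tau_fixed = 1)
  X <- cbind(1, x)
  A <- crossprod(X) + diag(0.001, 2)           # posterior precision (tau = 1)
  mpost <- solve(A, crossprod(X, y))
  Vpost <- solve(A)
  for (k in 1:2) {
    draws <- if (k == 1) dr$alpha else dr$beta
    mcse <- sd(draws) / sqrt(effective_sample_size(matrix(draws, ncol = 1)))
    expect_lt(abs(mean(draws) - mpost[k]), 3 * mcse + 1e-8)
    expect_equal(sd(draws), sqrt(Vpost[k, k]), tolerance = 0.1)
  }
})

test_that("prior-only sampling reproduces the stated prior moments", {
  cfg <- mcmc_config(chains = 1, iterations = 22000, burn_in = 1000,
                     thin = 1, seed = 6)
  dr <- colonywatch:::sample_gaussian_edge(numeric(0), numeric(0),
                                           site = NULL, prior_spec(), cfg,
                                           chain_seed = 7)
  # alpha, beta ~ N(0, precision 0.001): sd = sqrt(1000)
  for (v in list(dr$alpha, dr$beta)) {
    expect_lt(abs(mean(v)) / (sd(v) / sqrt(length(v))), 4)
    expect_equal(sd(v), sqrt(1000), tolerance = 0.05)
  }
  drb <- colonywatch:::sample_bernoulli_edge(numeric(0), numeric(0),
                                             site = NULL, prior_spec(), cfg,
                                             chain_seed = 8)
  expect_equal(sd(drb$beta), sqrt(1000), tolerance = 0.05)
})

test_that("a large-n Bernoulli edge concentrates at the logistic ML estimate", {
  set.seed(30)
  n <- 5000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 0.5 * x))
  cfg <- mcmc_config(chains = 1, iterations = 6000, burn_in = 1500, thin = 1,
                     seed = 3)
  dr <- colonywatch:::sample_bernoulli_edge(y, x, site = NULL, prior_spec(),
                                            cfg, chain_seed = 11)
  ml <- logistic_ml_oracle(cbind(1, x), y)
  expect_lt(abs(mean(dr$alpha) - ml[1]), 0.05)
  expect_lt(abs(mean(dr$beta) - ml[2]), 0.05)
})

test_that("MCMC fits are reproducible and flag convergence", {
  d <- make_path_data(seed = 3)
  pw <- build_pathways()[[2]]
  f1 <- mcmc_fit(pw, d, config = tiny_cfg(seed = 9))
  f2 <- mcmc_fit(pw, d, config = tiny_cfg(seed = 9))
  expect_identical(f1$edges[[1]]$beta, f2$edges[[1]]$beta)
  expect_identical(f1$pathway_draws, f2$pathway_draws)
  expect_true(all(c("rhat", "ess") %in% names(f1$diagnostics)))
  # pathway draws are the product of the edge draws
  expect_equal(f1$pathway_draws,
               f1$edges[[1]]$beta * f1$edges[[2]]$beta)
})

test_that("pathway estimates compose edge coefficients multiplicatively", {
  d <- make_path_data(n_site = 40, per_site = 5, b_ret = 0.5, b_succ = 0.4,
                      seed = 14)
  pw2 <- build_pathways()[[2]]
  fit <- mcmc_fit(pw2, d, config = mcmc_config(chains = 2, iterations = 8000,
                                               burn_in = 2000, thin = 2,
                                               seed = 4))
  est <- pathway_estimate(fit)
  # single-edge pathway: estimate equals the edge coefficient summary
  pw1 <- build_pathways()[[1]]
  fit1 <- mcmc_fit(pw1, d, config = tiny_cfg(seed = 5))
  est1 <- pathway_estimate(fit1)
  expect_equal(est1$estimate, mean(fit1$edges[[1]]$beta))
  expect_equal(est1$estimate, est1$direct_estimate)
  # product of generating effects: quality -> return (0.5 on z scale)
  # times return -> success; posterior mean in a sane band around it
  expect_gt(est$estimate, 0)
  expect_true(est$pct_same_sign >= 50 && est$pct_same_sign <= 100)
  expect_true(est$ci_lo <= median(as.vector(fit$pathway_draws)) &&
                median(as.vector(fit$pathway_draws)) <= est$ci_hi)
})

test_that("the same-sign share of a symmetric null posterior is near 50", {
  d <- make_path_data(n_site = 30, per_site = 3, b_ret = 0, b_succ = 0,
                      seed = 22)
  pw <- build_pathways()[[1]]
  fit <- mcmc_fit(pw, d, config = tiny_cfg(seed = 2))
  est <- pathway_estimate(fit)
  expect_lt(est$pct_same_sign, 75)
  expect_gte(est$pct_same_sign, 50)
})

test_that("null-signal credible intervals cover zero in >= 90% of replicates", {
  covered <- 0
  for (r in 1:20) {
    d <- make_path_data(n_site = 25, per_site = 2, b_ret = 0, b_succ = 0,
                        seed = 400 + r)
    fit <- suppressWarnings(mcmc_fit(
      build_pathways()[[1]], d,
      config = mcmc_config(chains = 2, iterations = 4000, burn_in = 800,
                           thin = 2, seed = r)))
    est <- pathway_estimate(fit)
    if (est$ci_lo < 0 && est$ci_hi > 0) covered <- covered + 1
  }
  expect_gte(covered, 18)
})
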