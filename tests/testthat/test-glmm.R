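test_that("a Gaussian model with no random terms collapses to least squares", {
  set.seed(10)
  d <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
  d$y <- 1 + 0.5 * d$x1 - 0.3 * d$x2 + rnorm(50)
  spec <- model_spec("y", c("x1", "x2"), random = list())
  fit <- fit_mixed(spec, d)
  beta_ols <- ols_oracle(cbind(1, d$x1, d$x2), d$y)
  expect_equal(fit$coefficients$estimate, beta_ols, tolerance = 1e-10)
})

test_that("a Bernoulli model with no random terms matches Newton-Raphson ML", {
  set.seed(11)
  d <- data.frame(x = rnorm(80))
  d$y <- rbinom(80, 1, plogis(0.4 + 0.8 * d$x))
  spec <- model_spec("y", "x", random = list(), family = "binomial")
  fit <- fit_mixed(spec, d)
  beta_ml <- logistic_ml_oracle(cbind(1, d$x), d$y)
  expect_equal(fit$coefficients$estimate, beta_ml, tolerance = 1e-6)
})

test_that("Laplace marginal log-likelihood matches quadrature and lme4", {
  fx <- quadrature_fixture()
  la <- laplace_loglik(c(0.3, 0.6), 0.05, fx$y, fx$m, fx$X, fx$group)
  gq <- ghq_loglik(c(0.3, 0.6), 0.05, fx$y, fx$m, fx$X, fx$group)
  expect_equal(la, gq, tolerance = 1e-6)
  # at larger random-effect SD the approximation degrades gracefully
  la2 <- laplace_loglik(c(0.3, 0.6), 0.5, fx$y, fx$m, fx$X, fx$group)
  gq2 <- ghq_loglik(c(0.3, 0.6), 0.5, fx$y, fx$m, fx$X, fx$group)
  expect_equal(la2, gq2, tolerance = 1e-3)
  # sigma = 0 collapses to the plain binomial log-likelihood
  expect_equal(laplace_loglik(c(0.3, 0.6), 0, fx$y, fx$m, fx$X, fx$group),
               sum(dbinom(fx$y, fx$m, plogis(0.3 + 0.6 * fx$x), log = TRUE)))
})

test_that("Wald intervals are estimate +/- 1.96 SE and drive significance", {
  d <- make_lmm_data(seed = 5)
  fit <- fit_mixed(model_spec("y", c("x1", "x2")), d)
  ci <- confint_fixed(fit, method = "wald")
  expect_equal(ci$ci_lo, fit$coefficients$estimate -
                 qnorm(0.975) * fit$coefficients$se)
  expect_equal(ci$ci_hi, fit$coefficients$estimate +
                 qnorm(0.975) * fit$coefficients$se)
  # x1 carries a 1-SD effect, x2 none
  expect_true(ci$significant[ci$term == "x1"])
  expect_false(ci$significant[ci$term == "x2"])
  prof <- confint_fixed(fit, method = "profile")
  expect_true(all(prof$ci_lo < prof$ci_hi))
  expect_true(prof$significant[prof$term == "x1"])
})

test_that("the two-step AIC rule is applied exactly on constructed tables", {
  tab <- data.frame(label = c("A", "B"), aic = c(100, 103), k = c(3, 4))
  sel <- apply_aic_rule(tab)
  expect_equal(sel$chosen, "A")
  expect_equal(sel$rule, "delta>2")
  # within 2 units the more parsimonious (nested) model wins
  tab2 <- data.frame(label = c("B", "A"), aic = c(100, 101.5), k = c(4, 3))
  sel2 <- apply_aic_rule(tab2)
  expect_equal(sel2$chosen, "A")
  expect_equal(sel2$rule, "parsimony")
  # identical AICs and k: deterministic lexicographic tie-break
  tab3 <- data.frame(label = c("zeta", "alpha"), aic = c(100, 100), k = c(3, 3))
  expect_equal(apply_aic_rule(tab3)$chosen, "alpha")
})

test_that("candidate enumeration respects marginality", {
  cands <- enumerate_candidates("y", c("x1", "x2"), interactions = "all2")
  labels <- vapply(cands, colonywatch:::spec_label, "")
  expect_equal(length(cands), 5)  # 1, x1, x2, x1+x2, x1+x2+x1:x2
  expect_true("y ~ x1 + x2 + x1:x2" %in% labels)
  expect_false(any(grepl("^y ~ x1:x2$", labels)))
  # three covariates with all interactions: 3-way requires all 2-way margins
  c3 <- enumerate_candidates("y", c("x1", "x2", "x3"), interactions = "all23")
  lab3 <- vapply(c3, colonywatch:::spec_label, "")
  full <- lab3[grepl("x1:x2:x3", lab3)]
  expect_true(all(grepl("x1:x2", full) & grepl("x1:x3", full) &
                    grepl("x2:x3", full)))
})

test_that("AIC selection recovers a known fixed structure and compares fairly", {
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    d <- make_lmm_data(n_groups = 30, per_group = 4, beta = c(1, 0, 0),
                       seed = 100 + r)
    cands <- enumerate_candidates("y", c("x1", "x2", "x3"))
    sel <- aic_select(cands, d)
    if (sel$chosen$label == "y ~ x1") hits <- hits + 1
  }
  expect_gte(hits, 0.7 * n_rep)
  # unequal rows across candidates are rejected
  d2 <- make_lmm_data(seed = 7)
  s1 <- model_spec("y", "x1")
  d_bad <- d2
  d_bad$x1[1] <- NA
  expect_error(fit_mixed(s1, d_bad), "missing values")
})

test_that("random-structure selection prefers the generating structure", {
  d <- make_lmm_data(n_groups = 40, per_group = 6, beta = c(1, 0, 0),
                     sd_group = 1.5, seed = 21)
  spec <- model_spec("y", "x1")
  sel <- random_structure_select(spec, d)
  expect_true(sel$structure %in% c("intercept", "intercept_slope",
                                   "intercept_slope_indep"))
  expect_true(all(c("intercept", "slope") %in% sel$table$label))
  # near-zero group variance: boundary fits are flagged
  d0 <- make_lmm_data(n_groups = 10, per_group = 3, sd_group = 0, seed = 3)
  sel0 <- random_structure_select(model_spec("y", "x1"), d0)
  expect_true(any(sel0$table$singular))
})

test_that("Nakagawa R-squared behaves at its analytic limits", {
  d <- make_lmm_data(seed = 9)
  # single-level Gaussian model: marginal equals classical R^2
  fit <- fit_mixed(model_spec("y", "x1", random = list()), d)
  lmf <- lm(y ~ x1, data = d)
  r2_classic <- summary(lmf)$r.squared
  expect_equal(fit$r2_marginal, r2_classic, tolerance = 1e-8)
  expect_equal(fit$r2_marginal, fit$r2_conditional)
  # null fixed model: marginal ~ 0
  fit0 <- fit_mixed(model_spec("y", character()), d)
  expect_lt(fit0$r2_marginal, 1e-10)
  # conditional >= marginal, both in [0, 1]
  fitm <- fit_mixed(model_spec("y", "x1"), d)
  expect_gte(fitm$r2_conditional, fitm$r2_marginal)
  expect_true(fitm$r2_conditional <= 1 && fitm$r2_marginal >= 0)
  # AIC identity
  expect_equal(fitm$AIC, 2 * fitm$df - 2 * fitm$logLik)
})

test_that("adding a useless term never decreases -2 logLik and costs 2/parameter", {
  d <- make_lmm_data(seed = 13)
  f1 <- fit_mixed(model_spec("y", "x1"), d)
  f2 <- fit_mixed(model_spec("y", c("x1", "x2")), d)
  expect_gte(f2$logLik, f1$logLik - 1e-8)
  expect_equal(f2$df, f1$df + 1)
  expect_equal(f2$AIC - f1$AIC, 2 - 2 * (f2$logLik - f1$logLik))
})

test_that("KS normality check matches enumeration and detects non-normality", {
  x10 <- c(-1.3, -0.8, -0.45, -0.2, 0.0, 0.15, 0.4, 0.7, 1.1, 1.9)
  res <- ks_normality(x10)
  D_oracle <- ks_enumeration_oracle(
    x10, function(v) pnorm(v, mean(x10), sd(x10)))
  expect_equal(res$D, D_oracle, tolerance = 1e-12)
  # near-perfect normal quantiles: D near 0
  xq <- qnorm(ppoints(500))
  expect_lt(ks_normality(xq)$D, 0.02)
  # clearly non-normal samples are rejected in the majority of replicates:
  # a skewed exponential at n = 200, and a uniform once n is large enough
  # for its modest distance from the moment-fitted normal to register
  rej_exp <- rej_unif <- 0
  for (s in 1:5) {
    set.seed(s)
    if (ks_normality(rexp(200))$p < 0.05) rej_exp <- rej_exp + 1
    if (ks_normality(runif(1000))$p < 0.05) rej_unif <- rej_unif + 1
  }
  expect_gte(rej_exp, 3)
  expect_gte(rej_unif, 3)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(1:4), ">= 5")
})

test_that("collinearity screen flags |r| > 0.7", {
  set.seed(2)
  a <- rnorm(100)
  d <- data.frame(a = a, b = a + rnorm(100, 0, 0.1), c = rnorm(100))
  expect_true(collinearity_screen(d, c("a", "b"))$flag)
  expect_false(collinearity_screen(d, c("a", "c"))$flag)
})
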