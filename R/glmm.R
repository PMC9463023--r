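# Mixed-model layer: model specifications, lme4-backed fitting (maximum
# likelihood throughout, so models differing in fixed effects are AIC-
# comparable), Wald/profile confidence intervals, Nakagawa R-squared and
# residual diagnostics.

#' Specify a mixed model
#'
#' @param response response variable name.  Distribution is set by
#'   \code{family}; binomial responses with aggregated trials name their
#'   numerator/denominator via \code{trials}.
#' @param fixed character vector of main-effect covariate names.
#' @param interactions list of character vectors, each an interaction among
#'   covariates listed in \code{fixed}.
#' @param random named list: grouping factor -> structure, one of
#'   \code{"intercept"}, \code{"intercept_slope"} (correlated),
#'   \code{"intercept_slope_indep"}, \code{"slope"}.
#' @param family \code{"gaussian"} (identity link) or \code{"binomial"}
#'   (logit link).
#' @param trials for an aggregated binomial response: \code{c(num, den)}
#'   column names (numerator successes and total trials); \code{NULL} for a
#'   Bernoulli 0/1 response.
#' @param slope_var covariate receiving the random slope where the random
#'   structure includes one (defaults to the first fixed covariate).
#' @return object of class \code{cw_spec}.
#' @export
model_spec <- function(response, fixed = character(), interactions = list(),
                       random = list(site_id = "intercept"),
                       family = c("gaussian", "binomial"), trials = NULL,
                       slope_var = NULL) {
  family <- match.arg(family)
  if (length(interactions)) {
    for (ia in interactions)
      if (!all(ia %in% fixed))
        stopf("interaction (%s) involves covariates not in the main effects",
              paste(ia, collapse = ":"))
  }
  structures <- c("intercept", "intercept_slope", "intercept_slope_indep", "slope")
  for (st in random)
    if (!st %in% structures)
      stopf("unknown random structure '%s'", st)
  if (is.null(slope_var) && length(fixed)) slope_var <- fixed[1]
  out <- list(response = response, fixed = fixed, interactions = interactions,
              random = random, family = family, trials = trials,
              slope_var = slope_var)
  class(out) <- "cw_spec"
  out
}

# deterministic, human-readable model label from the term set
spec_label <- function(spec) {
  terms <- c(spec$fixed, vapply(spec$interactions, paste, "", collapse = ":"))
  if (!length(terms)) terms <- "1"
  paste0(spec$response, " ~ ", paste(terms, collapse = " + "))
}

spec_formula <- function(spec) {
  lhs <- if (spec$family == "binomial" && !is.null(spec$trials))
    sprintf("cbind(%s, %s - %s)", spec$trials[1], spec$trials[2], spec$trials[1])
  else spec$response
  terms <- c(spec$fixed, vapply(spec$interactions, paste, "", collapse = ":"))
  if (!length(terms)) terms <- "1"
  re <- character(0)
  for (g in names(spec$random)) {
    re <- c(re, switch(spec$random[[g]],
      intercept = sprintf("(1 | %s)", g),
      intercept_slope = sprintf("(1 + %s | %s)", spec$slope_var, g),
      intercept_slope_indep = sprintf("(1 | %s) + (0 + %s | %s)",
                                      g, spec$slope_var, g),
      slope = sprintf("(0 + %s | %s)", spec$slope_var, g)))
  }
  as.formula(paste(lhs, "~", paste(c(terms, re), collapse = " + ")))
}

#' Fit a (generalized) linear mixed model by maximum likelihood
#'
#' Gaussian responses use \code{lme4::lmer} with \code{REML = FALSE} (exact
#' ML, so fixed-effect AIC comparisons are valid); binomial responses use
#' \code{lme4::glmer} (Laplace-approximated marginal likelihood).  With no
#' random terms the fit collapses to \code{lm}/\code{glm}.  Non-convergence
#' and singular (boundary) random-effect fits are flagged, never silent.
#'
#' @param spec a \code{cw_spec} from \code{\link{model_spec}}.
#' @param data data.frame containing every variable in the spec; rows with
#'   missing values in used variables are an error (candidate comparability).
#' @return object of class \code{cw_fit}: coefficient table with Wald 95\%
#'   CIs, variance components, log-likelihood, AIC, marginal/conditional
#'   R-squared, convergence and singularity flags.
#' @export
fit_mixed <- function(spec, data) {
  stopifnot(inherits(spec, "cw_spec"))
  vars <- unique(c(spec$response, spec$fixed, names(spec$random),
                   spec$trials, spec$slope_var))
  vars <- intersect(vars, names(data))
  if (anyNA(data[, vars]))
    stopf("data error: missing values in model variables (%s)",
          paste(vars[vapply(data[, vars, drop = FALSE], anyNA, TRUE)],
                collapse = ", "))
  form <- spec_formula(spec)
  has_re <- length(spec$random) > 0
  warn <- character(0)
  fit <- withCallingHandlers({
    if (spec$family == "gaussian") {
      if (has_re) lme4::lmer(form, data = data, REML = FALSE)
      else lm(form, data = data)
    } else {
      if (has_re) lme4::glmer(form, data = data, family = binomial)
      else glm(form, data = data, family = binomial)
    }
  }, warning = function(w) {
    warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
  }, message = function(m) {
    # lme4 signals boundary fits as messages; keep them on the fit object
    warn <<- c(warn, conditionMessage(m)); invokeRestart("muffleMessage")
  })

  is_mer <- inherits(fit, "merMod")
  est <- if (is_mer) lme4::fixef(fit) else coef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))[seq_along(est)]
  ci <- cbind(est - qnorm(0.975) * se, est + qnorm(0.975) * se)
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), ci_lo = ci[, 1], ci_hi = ci[, 2],
                      significant = ci[, 1] * ci[, 2] > 0,
                      stringsAsFactors = FALSE)
  ll <- logLik(fit)
  converged <- TRUE; singular <- FALSE
  if (is_mer) {
    converged <- length(fit@optinfo$conv$lme4) == 0 &&
      !any(grepl("failed to converge", warn))
    singular <- lme4::isSingular(fit, tol = 1e-4)
  }
  r2 <- r_squared_nakagawa_fit(fit, spec)
  out <- list(spec = spec, label = spec_label(spec), fit = fit,
              coefficients = coefs,
              varcomp = if (is_mer) as.data.frame(lme4::VarCorr(fit)) else NULL,
              logLik = as.numeric(ll), df = attr(ll, "df"),
              AIC = AIC(fit), n = stats::nobs(fit),
              r2_marginal = unname(r2[1]), r2_conditional = unname(r2[2]),
              converged = converged, singular = singular, warnings = warn)
  class(out) <- "cw_fit"
  out
}

#' @export
print.cw_fit <- function(x, ...) {
  cat(x$label, sprintf(" [%s]\n", x$spec$family))
  print(x$coefficients, row.names = FALSE, digits = 3)
  cat(sprintf("AIC %.2f  logLik %.2f (df %d)  R2m %.3f  R2c %.3f%s%s\n",
              x$AIC, x$logLik, x$df, x$r2_marginal, x$r2_conditional,
              if (!x$converged) "  [NOT CONVERGED]" else "",
              if (x$singular) "  [singular fit]" else ""))
  invisible(x)
}

#' Confidence intervals for fixed effects
#'
#' Profile-likelihood intervals by default; on profile failure the Wald
#' interval is substituted and the fallback recorded.  A term is flagged
#' significant when its interval excludes zero.
#'
#' @param fit a \code{cw_fit}.
#' @param method \code{"profile"} or \code{"wald"}.
#' @param level confidence level.
#' @return data.frame term/estimate/ci_lo/ci_hi/significant/method.
#' @export
confint_fixed <- function(fit, method = c("profile", "wald"), level = 0.95) {
  method <- match.arg(method)
  est <- fit$coefficients$estimate
  names(est) <- fit$coefficients$term
  if (method == "wald") {
    z <- qnorm(1 - (1 - level) / 2)
    ci <- cbind(est - z * fit$coefficients$se, est + z * fit$coefficients$se)
    used <- "wald"
  } else {
    ci <- tryCatch({
      if (inherits(fit$fit, "merMod")) {
        cc <- suppressMessages(confint(fit$fit, parm = "beta_",
                                       method = "profile", level = level,
                                       quiet = TRUE))
      } else {
        cc <- suppressMessages(confint(fit$fit, level = level))
      }
      cc[fit$coefficients$term, , drop = FALSE]
    }, error = function(e) NULL)
    if (is.null(ci) || anyNA(ci)) {
      z <- qnorm(1 - (1 - level) / 2)
      ci <- cbind(est - z * fit$coefficients$se, est + z * fit$coefficients$se)
      used <- "wald (profile failed)"
    } else used <- "profile"
  }
  data.frame(term = fit$coefficients$term, estimate = unname(est),
             ci_lo = ci[, 1], ci_hi = ci[, 2],
             significant = ci[, 1] * ci[, 2] > 0,
             method = used, row.names = NULL, stringsAsFactors = FALSE)
}

# Nakagawa & Schielzeth marginal/conditional R2 on a fitted model object.
# Random-effect variance uses the Johnson (2014) form mean(diag(Z S Z')),
# which handles random slopes; logit models add the pi^2/3 link variance.
r_squared_nakagawa_fit <- function(fit, spec) {
  if (inherits(fit, "merMod")) {
    X <- lme4::getME(fit, "X")
    var_f <- var(as.vector(X %*% lme4::fixef(fit)))
    vc <- lme4::VarCorr(fit)
    mm <- lme4::getME(fit, "mmList")
    var_re <- 0
    for (k in seq_along(mm)) {
      S <- as.matrix(vc[[k]])
      Zk <- as.matrix(mm[[k]])
      var_re <- var_re + mean(rowSums((Zk %*% S) * Zk))
    }
    var_eps <- if (spec$family == "gaussian") sigma(fit)^2 else pi^2 / 3
  } else {
    var_f <- var(fitted(if (inherits(fit, "glm")) fit else fit))
    if (inherits(fit, "glm")) {
      eta <- stats::predict(fit, type = "link")
      var_f <- var(eta)
      var_eps <- pi^2 / 3
    } else {
      var_eps <- var(stats::residuals(fit))
    }
    var_re <- 0
  }
  tot <- var_f + var_re + var_eps
  c(marginal = var_f / tot, conditional = (var_f + var_re) / tot)
}

#' Marginal and conditional R-squared of a mixed-model fit
#'
#' Fixed-effect variance over total (marginal) and fixed-plus-random over
#' total (conditional); the residual variance of a logit model is the
#' logistic link variance pi^2/3.
#'
#' @param fit a \code{cw_fit}.
#' @return named numeric \code{c(marginal, conditional)}.
#' @export
r_squared_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "cw_fit"))
  c(marginal = fit$r2_marginal, conditional = fit$r2_conditional)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Two-sided KS test of the values against a normal distribution with
#' moment-estimated mean and SD (the residual-normality screen used before
#' fitting Gaussian models).
#'
#' @param values numeric vector, at least 5 non-constant values.
#' @return list with \code{D} and \code{p}.
#' @export
ks_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5) stopf("need >= 5 values for the KS check")
  if (sd(values) == 0) stopf("degenerate input: constant values")
  kt <- suppressWarnings(ks.test(values, "pnorm", mean(values), sd(values)))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Pairwise collinearity screen
#'
#' Pearson correlations among candidate (standardized) covariates; any
#' absolute pairwise correlation above the cutoff flags the covariate set.
#'
#' @param data data.frame.
#' @param covariates column names to screen.
#' @param cutoff flag threshold (default 0.7).
#' @return list with \code{correlations} (matrix) and \code{flag}.
#' @export
collinearity_screen <- function(data, covariates, cutoff = 0.7) {
  cm <- stats::cor(data[, covariates, drop = FALSE], use = "complete.obs")
  off <- abs(cm[upper.tri(cm)])
  list(correlations = cm, flag = any(off > cutoff), cutoff = cutoff)
}
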