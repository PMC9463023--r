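# Bayesian structural path analysis: five fixed pathways from site quality
# to breeding success.  Each pathway is a chain of single-predictor
# regressions with a site random intercept; the Bernoulli-logit endpoint is
# always breeding success.  A pathway's coefficient is the product of its
# standardized edge coefficients (the classic path-analysis composition
# rule); the direct endpoint coefficient is also reported for transparency.

#' The five candidate pathways
#'
#' Each pathway starts at site quality and ends at breeding success:
#' (1) quality -> success; (2) quality -> return date -> success;
#' (3) quality -> lay date -> success; (4) quality -> occupancy frequency ->
#' lay date -> success; (5) quality -> return date -> occupancy frequency ->
#' lay date -> success.  Variables are the standardized columns
#' \code{quality_z}, \code{return_z}, \code{freq_z}, \code{laydate_z} plus
#' the binary \code{success} endpoint (left 0/1 under the Bernoulli-logit
#' likelihood; standardizing a Bernoulli response is not model-coherent).
#'
#' @return list of five pathway specs (id, label, chain, edges).
#' @export
build_pathways <- function() {
  chains <- list(
    c("quality_z", "success"),
    c("quality_z", "return_z", "success"),
    c("quality_z", "laydate_z", "success"),
    c("quality_z", "freq_z", "laydate_z", "success"),
    c("quality_z", "return_z", "freq_z", "laydate_z", "success"))
  labels <- c(
    "Breeding success ~ site quality",
    "Breeding success ~ site quality + return date",
    "Breeding success ~ site quality + lay date",
    "Breeding success ~ site quality + occupancy frequency + lay date",
    "Breeding success ~ site quality + return date + occupancy frequency + lay date")
  lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    edges <- lapply(seq_len(length(ch) - 1), function(k) {
      list(predictor = ch[k], response = ch[k + 1],
           family = if (ch[k + 1] == "success") "bernoulli" else "gaussian")
    })
    structure(list(id = i, label = labels[i], chain = ch, edges = edges),
              class = "cw_pathway")
  })
}

#' Sample one pathway's regressions by MCMC
#'
#' Runs every edge regression of the pathway (Gaussian edges by conjugate
#' Gibbs, the Bernoulli endpoint by adaptive Metropolis-within-Gibbs), with
#' the configured chains, burn-in and thinning.  Chains are seeded
#' deterministically from the config seed, pathway id, edge and chain
#' index.
#'
#' @param pathway one element of \code{\link{build_pathways}}.
#' @param data data.frame with the standardized chain variables and
#'   \code{site_id}; no missing values allowed in chain variables.
#' @param priors a \code{\link{prior_spec}}.
#' @param config a \code{\link{mcmc_config}}.
#' @return object of class \code{cw_posterior}: per-edge draw matrices
#'   (kept x chains) for alpha, beta and the site-effect SD, plus R-hat/ESS
#'   diagnostics and a convergence flag (R-hat above 1.05 on any monitored
#'   variable).
#' @export
mcmc_fit <- function(pathway, data, priors = prior_spec(),
                     config = mcmc_config(profile = "fast")) {
  stopifnot(inherits(pathway, "cw_pathway"))
  vars <- setdiff(pathway$chain, "success")
  used <- c(vars, if ("success" %in% pathway$chain) "success", "site_id")
  if (nrow(data) > 0 && anyNA(data[, intersect(used, names(data))]))
    stopf("data error: missing values in pathway variables")
  edges <- vector("list", length(pathway$edges))
  for (k in seq_along(pathway$edges)) {
    e <- pathway$edges[[k]]
    y <- if (nrow(data)) data[[e$response]] else numeric(0)
    x <- if (nrow(data)) data[[e$predictor]] else numeric(0)
    site <- if (nrow(data)) data$site_id else NULL
    draws <- lapply(seq_len(config$chains), function(ch) {
      seed <- substream_seed(config$seed,
                             sprintf("path%d-edge%d-chain%d", pathway$id, k, ch))
      if (e$family == "bernoulli")
        sample_bernoulli_edge(y, x, site, priors, config, seed)
      else
        sample_gaussian_edge(y, x, site, priors, config, seed)
    })
    bind <- function(name) do.call(cbind, lapply(draws, `[[`, name))
    edges[[k]] <- list(edge = sprintf("%s ~ %s", e$response, e$predictor),
                       family = e$family,
                       alpha = bind("alpha"), beta = bind("beta"),
                       sd_site = bind("sd_site"),
                       sigma = if (e$family == "gaussian") bind("sigma") else NULL)
  }
  # pathway coefficient: per-draw product of edge betas
  prod_draws <- edges[[1]]$beta
  if (length(edges) > 1)
    for (k in 2:length(edges)) prod_draws <- prod_draws * edges[[k]]$beta
  monitored <- list()
  for (k in seq_along(edges)) {
    monitored[[paste0("alpha[", edges[[k]]$edge, "]")]] <- edges[[k]]$alpha
    monitored[[paste0("beta[", edges[[k]]$edge, "]")]] <- edges[[k]]$beta
  }
  monitored[["pathway"]] <- prod_draws
  diag_tab <- data.frame(
    variable = names(monitored),
    rhat = vapply(monitored, function(m)
      if (ncol(m) >= 2) gelman_rubin(m) else NA_real_, 0),
    ess = vapply(monitored, effective_sample_size, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(pathway = pathway, edges = edges, pathway_draws = prod_draws,
              config = config, priors = priors, diagnostics = diag_tab,
              converged = all(is.na(diag_tab$rhat) | diag_tab$rhat <= 1.05))
  class(out) <- "cw_posterior"
  if (!out$converged)
    warning(sprintf("pathway %d: R-hat above 1.05 on %s", pathway$id,
                    paste(diag_tab$variable[which(diag_tab$rhat > 1.05)],
                          collapse = ", ")), call. = FALSE)
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance decomposition; values near 1
#' indicate convergence (the acceptance bar used here is 1.05).
#'
#' @param chains matrix of draws, one column per chain (equal lengths).
#' @return the R-hat scalar.
#' @export
gelman_rubin <- function(chains) {
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2) stopf("need >= 2 chains for the Gelman-Rubin statistic")
  means <- colMeans(chains)
  W <- mean(apply(chains, 2, var))
  B_over_n <- var(means)
  if (W == 0 || B_over_n == 0) return(1)  # identical chains have converged
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-time based: per chain, the integrated autocorrelation
#' time is estimated with Geyer's initial positive sequence and the chain's
#' n is deflated by it; chain-wise ESS values are summed.
#'
#' @param chains matrix (or vector) of draws, one column per chain.
#' @return total effective sample size.
#' @export
effective_sample_size <- function(chains) {
  chains <- as.matrix(chains)
  per_chain <- function(x) {
    n <- length(x)
    if (sd(x) == 0) stopf("constant chain: ESS undefined")
    lag_max <- min(n - 1, 2000)
    rho <- as.vector(acf(x, lag.max = lag_max, plot = FALSE,
                         demean = TRUE)$acf)[-1]
    # Geyer initial positive sequence over lag pairs
    tau <- 1
    k <- 1
    while (k + 1 <= length(rho)) {
      g <- rho[k] + rho[k + 1]
      if (g < 0) break
      tau <- tau + 2 * g
      k <- k + 2
    }
    n / tau
  }
  sum(apply(chains, 2, per_chain))
}

#' Summarize a pathway posterior
#'
#' The pathway coefficient is, per retained draw, the product of the
#' standardized edge coefficients along the chain.  Reported: posterior
#' mean, 95\% credible interval (quantiles), and the percentage of the
#' posterior sharing the sign of the mean.  The direct coefficient of the
#' final edge is reported alongside.
#'
#' @param posterior a \code{cw_posterior} from \code{\link{mcmc_fit}}.
#' @return one-row data.frame.
#' @export
pathway_estimate <- function(posterior) {
  stopifnot(inherits(posterior, "cw_posterior"))
  d <- as.vector(posterior$pathway_draws)
  est <- mean(d)
  ci <- unname(quantile(d, c(0.025, 0.975)))
  same <- 100 * mean(sign(d) == sign(est))
  last <- posterior$edges[[length(posterior$edges)]]
  dd <- as.vector(last$beta)
  data.frame(pathway = posterior$pathway$label,
             estimate = est, ci_lo = ci[1], ci_hi = ci[2],
             pct_same_sign = same,
             direct_estimate = mean(dd),
             direct_ci_lo = unname(quantile(dd, 0.025)),
             direct_ci_hi = unname(quantile(dd, 0.975)),
             stringsAsFactors = FALSE)
}

#' Fit all five pathways
#'
#' @param data standardized analysis table (columns \code{quality_z},
#'   \code{return_z}, \code{freq_z}, \code{laydate_z}, \code{success},
#'   \code{site_id}).
#' @param priors a \code{\link{prior_spec}}.
#' @param config a \code{\link{mcmc_config}}.
#' @return list: \code{pathways} (summary table in pathway order),
#'   \code{diagnostics} (per-variable R-hat/ESS across all pathway models),
#'   \code{posteriors} (list of \code{cw_posterior}), \code{converged}.
#' @export
fit_path_analysis <- function(data, priors = prior_spec(),
                              config = mcmc_config(profile = "fast")) {
  specs <- build_pathways()
  posteriors <- lapply(specs, mcmc_fit, data = data, priors = priors,
                       config = config)
  tab <- do.call(rbind, lapply(posteriors, pathway_estimate))
  diags <- do.call(rbind, lapply(posteriors, function(p) {
    d <- p$diagnostics
    d$pathway <- p$pathway$id
    d
  }))
  list(pathways = tab, diagnostics = diags, posteriors = posteriors,
       converged = all(vapply(posteriors, `[[`, TRUE, "converged")))
}
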