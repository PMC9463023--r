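# AIC-based model selection: the two-step rule (clear winner at dAIC > 2,
# otherwise the most parsimonious un-nested candidate), applied to fixed
# effects and to the four standard random-effect structures.

# term signature of a spec: sorted mains and interactions, for nesting tests
spec_terms <- function(spec) {
  sort(c(spec$fixed, vapply(spec$interactions, function(ia)
    paste(sort(ia), collapse = ":"), "")))
}

terms_nested <- function(a, b) all(a %in% b)  # a nested in b

#' Apply the two-step AIC selection rule to a candidate table
#'
#' If the AIC gap between the best and the next-best model exceeds 2, the
#' lowest-AIC model wins.  Otherwise, among all models within 2 AIC units of
#' the best, the most parsimonious is selected (fewest parameters; a model
#' nested in a rival is preferred to it); remaining ties break
#' deterministically by lexicographic model label.
#'
#' @param table data.frame with columns \code{label}, \code{aic}, \code{k}
#'   (parameter count) and optionally \code{terms} (list column of term
#'   signatures, used for nesting).
#' @return list: \code{chosen} (label), \code{rule} ("delta>2" or
#'   "parsimony"), \code{table} (with delta_aic, ordered).
#' @export
apply_aic_rule <- function(table) {
  stopifnot(all(c("label", "aic", "k") %in% names(table)))
  tab <- table[order(table$aic, table$k, table$label), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  if (nrow(tab) == 1 || tab$delta_aic[2] > 2) {
    return(list(chosen = tab$label[1], rule = "delta>2", table = tab))
  }
  near <- tab[tab$delta_aic < 2, , drop = FALSE]
  if (nrow(near) == 0) near <- tab[1, , drop = FALSE]
  near <- near[order(near$k, near$label), , drop = FALSE]
  list(chosen = near$label[1], rule = "parsimony", table = tab)
}

#' Enumerate fixed-effect candidate models
#'
#' All subsets of the main effects; when interactions are requested, every
#' admissible subset of interaction terms (those whose covariates are all
#' present) is added, respecting marginality.
#'
#' @param response response name.
#' @param covariates main-effect covariate names.
#' @param interactions list of character vectors (candidate interactions),
#'   or \code{"all2"} / \code{"all23"} for all two-way (and three-way)
#'   interactions among the covariates.
#' @param ... passed to \code{\link{model_spec}} (family, trials, random).
#' @return list of \code{cw_spec}.
#' @export
enumerate_candidates <- function(response, covariates, interactions = list(),
                                 ...) {
  if (identical(interactions, "all2") || identical(interactions, "all23")) {
    ia <- combn(covariates, 2, simplify = FALSE)
    if (identical(interactions, "all23") && length(covariates) >= 3)
      ia <- c(ia, combn(covariates, 3, simplify = FALSE))
    interactions <- ia
  }
  specs <- list()
  n <- length(covariates)
  for (i in 0:(2^n - 1)) {
    mains <- covariates[bitwAnd(i, 2^(seq_len(n) - 1)) > 0]
    admissible <- Filter(function(ia) all(ia %in% mains), interactions)
    m <- length(admissible)
    for (j in 0:(2^max(m, 0) - 1)) {
      ints <- if (m) admissible[bitwAnd(j, 2^(seq_len(m) - 1)) > 0] else list()
      # marginality: a 3-way interaction requires its 2-way margins
      ok <- all(vapply(ints, function(ia) {
        if (length(ia) < 3) return(TRUE)
        subs <- combn(ia, 2, simplify = FALSE)
        all(vapply(subs, function(s) any(vapply(ints, setequal, TRUE, s)), TRUE))
      }, TRUE))
      if (ok) specs <- c(specs, list(model_spec(response, mains, ints, ...)))
    }
  }
  specs
}

#' Fit candidates and select by the two-step AIC rule
#'
#' All candidates are fitted by ML on the same rows (missing values are an
#' error, guaranteeing comparability).
#'
#' @param candidates list of \code{cw_spec}.
#' @param data data.frame.
#' @return list: \code{chosen} (a \code{cw_fit}), \code{rule},
#'   \code{table} (AIC table), \code{fits} (all \code{cw_fit}s by label).
#' @export
aic_select <- function(candidates, data) {
  fits <- lapply(candidates, fit_mixed, data = data)
  ns <- vapply(fits, function(f) f$n, 0)
  if (length(unique(ns)) > 1)
    stopf("comparability error: candidates fitted on unequal row counts (%s)",
          paste(unique(ns), collapse = ", "))
  labels <- vapply(fits, function(f) f$label, "")
  tab <- data.frame(label = labels,
                    aic = vapply(fits, function(f) f$AIC, 0),
                    k = vapply(fits, function(f) f$df, 0),
                    converged = vapply(fits, function(f) f$converged, TRUE),
                    stringsAsFactors = FALSE)
  tab$terms <- I(lapply(fits, function(f) spec_terms(f$spec)))
  sel <- apply_aic_rule(tab)
  names(fits) <- labels
  list(chosen = fits[[sel$chosen]], rule = sel$rule, table = sel$table,
       fits = fits)
}

#' Select the random-effect structure for a chosen fixed structure
#'
#' Refits the model with the four standard structures on the given grouping
#' factor -- random intercept, correlated intercept and slope, independent
#' intercept and slope, slope only -- and applies the same two-step AIC
#' rule.  Boundary (singular) fits are flagged in the table.
#'
#' @param spec the chosen fixed-effect \code{cw_spec}.
#' @param data data.frame.
#' @param group grouping factor to vary (default the first random term).
#' @param slope_var covariate for the random slope (default
#'   \code{spec$slope_var}).
#' @return as \code{\link{aic_select}}, with a \code{structure} column.
#' @export
random_structure_select <- function(spec, data, group = names(spec$random)[1],
                                    slope_var = spec$slope_var) {
  structures <- c("intercept", "intercept_slope", "intercept_slope_indep",
                  "slope")
  specs <- lapply(structures, function(st) {
    s <- spec
    s$random[[group]] <- st
    s$slope_var <- slope_var
    s
  })
  fits <- lapply(specs, fit_mixed, data = data)
  tab <- data.frame(label = structures,
                    aic = vapply(fits, function(f) f$AIC, 0),
                    k = vapply(fits, function(f) f$df, 0),
                    singular = vapply(fits, function(f) f$singular, TRUE),
                    converged = vapply(fits, function(f) f$converged, TRUE),
                    stringsAsFactors = FALSE)
  sel <- apply_aic_rule(tab)
  names(fits) <- structures
  list(chosen = fits[[sel$chosen]], structure = sel$chosen, rule = sel$rule,
       table = sel$table, fits = fits)
}
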