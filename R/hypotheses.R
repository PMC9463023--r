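# Hypothesis-level model sets: the two association models among occupancy
# measures, the site-quality models (site defense hypothesis), and the
# occupancy -> breeding models, each run through candidate enumeration and
# the two-step AIC rule.

#' Join metrics, breeding and site tables into a modeling table
#'
#' Merges on site and season, attaches season/year factors and the
#' "subcolony year" grouping, and standardizes quality, return day,
#' occupancy frequency, RTI and lay date within subcolony x season (the
#' grouping used before all model fitting).
#'
#' @param metrics output of \code{\link{compute_metrics}}.
#' @param breeding breeding table (site_id, season, lay_date, success).
#' @param sites site table (site_id, subcolony, quality).
#' @return data.frame with *_z columns, \code{year} and
#'   \code{subcolony_season} factors.  Site-seasons without a return date
#'   are dropped (counted in the \code{n_dropped} attribute).
#' @export
prepare_model_data <- function(metrics, breeding, sites) {
  d <- merge(metrics, breeding, by = c("site_id", "season"), all.x = TRUE)
  d <- merge(d, sites[, c("site_id", "quality")], by = "site_id")
  n0 <- nrow(d)
  d <- d[!is.na(d$return_day), ]
  attr_drop <- n0 - nrow(d)
  d$year <- factor(d$season)
  d$subcolony_season <- factor(paste(d$subcolony, d$season))
  grp <- d$subcolony_season
  zcol <- function(v) standardize(v, grp)$z
  d$quality_z <- zcol(d$quality)
  d$return_z <- zcol(d$return_day)
  d$freq_z <- zcol(d$occ_freq)
  d$rti_z <- zcol(d$rti)
  d$laydate_z <- if (all(is.na(d$lay_date))) NA_real_ else {
    out <- rep(NA_real_, nrow(d))
    ok <- !is.na(d$lay_date)
    out[ok] <- standardize(d$lay_date[ok], grp[ok])$z
    out
  }
  attr(d, "n_dropped") <- attr_drop
  d
}

#' Fit one hypothesis model set
#'
#' \describe{
#'   \item{assoc1}{occupancy frequency ~ return date (binomial, logit).}
#'   \item{assoc2}{RTI ~ return date * occupancy frequency (binomial,
#'     logit), including the two-way interaction.}
#'   \item{1}{site-quality models (subcolony 1 only): return day (Gaussian),
#'     occupancy frequency and RTI (binomial) each on quality x year.}
#'   \item{2a}{lay date ~ the three occupancy measures with all two- and
#'     three-way interactions (Gaussian).}
#'   \item{2b}{breeding success ~ the same terms (Bernoulli, logit).}
#' }
#' Each candidate set is every admissible term combination; selection uses
#' the two-step AIC rule; the winning fixed structure then has its random
#' structure selected over the four standard forms.
#'
#' @param data table from \code{\link{prepare_model_data}}.
#' @param hypothesis one of "assoc1", "assoc2", "1", "2a", "2b".
#' @param select_random also run random-structure selection on the winner.
#' @return for hypothesis "1", a named list of three selection results;
#'   otherwise one selection result (see \code{\link{aic_select}}).
#' @export
fit_hypothesis <- function(data, hypothesis = c("assoc1", "assoc2", "1",
                                                "2a", "2b"),
                           select_random = FALSE) {
  hypothesis <- match.arg(hypothesis)
  run <- function(cands, d) {
    sel <- aic_select(cands, d)
    if (select_random)
      sel$random_structure <- random_structure_select(sel$chosen$spec, d)
    sel
  }
  if (hypothesis == "assoc1") {
    d <- data[!is.na(data$occ_freq_num), ]
    cands <- enumerate_candidates(
      "occ_freq", "return_z", family = "binomial",
      trials = c("occ_freq_num", "occ_freq_den"),
      random = list(site_id = "intercept", subcolony_season = "intercept"))
    return(run(cands, d))
  }
  if (hypothesis == "assoc2") {
    d <- data[!is.na(data$rti_num), ]
    cands <- enumerate_candidates(
      "rti", c("return_z", "freq_z"), interactions = "all2",
      family = "binomial", trials = c("rti_num", "rti_den"),
      random = list(site_id = "intercept", subcolony_season = "intercept"))
    return(run(cands, d))
  }
  if (hypothesis == "1") {
    d <- data[data$subcolony == sort(unique(data$subcolony))[1], ]
    mk <- function(response, family, trials = NULL)
      enumerate_candidates(response, c("quality_z", "year"),
                           interactions = "all2", family = family,
                           trials = trials,
                           random = list(site_id = "intercept"))
    return(list(
      return_day = run(mk("return_day", "gaussian"), d),
      occ_freq = run(mk("occ_freq", "binomial",
                        c("occ_freq_num", "occ_freq_den")), d),
      rti = run(mk("rti", "binomial", c("rti_num", "rti_den")), d)))
  }
  covs <- c("return_z", "freq_z", "rti_z")
  if (hypothesis == "2a") {
    d <- data[!is.na(data$laydate_z), ]
    cands <- enumerate_candidates(
      "lay_date", covs, interactions = "all23", family = "gaussian",
      random = list(site_id = "intercept", subcolony_season = "intercept"))
    return(run(cands, d))
  }
  d <- data[!is.na(data$success), ]
  cands <- enumerate_candidates(
    "success", covs, interactions = "all23", family = "binomial",
    random = list(site_id = "intercept", subcolony_season = "intercept"))
  run(cands, d)
}

#' Assemble the standardized path-analysis table
#'
#' Subcolony-1 site-seasons with complete quality, return, frequency, lay
#' date and success; all continuous variables standardized over the whole
#' table (mean-centered, scaled), success left 0/1.  Optionally truncated
#' to a fixed number of rows (deterministic site/season order) to match a
#' target sample size.
#'
#' @param metrics,breeding,sites as in \code{\link{prepare_model_data}}.
#' @param subcolony which subcolony carries quality data.
#' @param n_rows optional row cap.
#' @return data.frame with quality_z, return_z, freq_z, laydate_z, success,
#'   site_id.
#' @export
build_path_data <- function(metrics, breeding, sites, subcolony = 1,
                            n_rows = NULL) {
  d <- merge(metrics, breeding, by = c("site_id", "season"))
  d <- merge(d, sites[, c("site_id", "quality")], by = "site_id")
  d <- d[d$subcolony == subcolony, ]
  d <- d[!is.na(d$return_day) & !is.na(d$lay_date) & !is.na(d$success), ]
  d <- d[order(d$season, d$site_id), ]
  if (!is.null(n_rows)) d <- head(d, n_rows)
  z <- function(v) (v - mean(v)) / sd(v)
  data.frame(site_id = d$site_id, season = d$season,
             quality_z = z(d$quality), return_z = z(d$return_day),
             freq_z = z(d$occ_freq), laydate_z = z(d$lay_date),
             success = d$success, stringsAsFactors = FALSE)
}
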