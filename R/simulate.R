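# Synthetic colony generator.
#
# The generator draws, per site and season: a latent return day, daily
# occupancy indicators from return to season end, and image-level presence
# counts (0/1/2) inside daylight, then lay date and breeding success from
# the realized occupancy under known coefficients.  It is the ground-truth
# test-bed for the metrics, mixed-model and path-analysis stages.

#' Ground-truth parameter set for the synthetic colony generator
#'
#' Defaults emulate the study system: two subcolonies (27 and 52 monitored
#' sites), three seasons of daytime time-lapse scoring at 15-min intervals,
#' mean first return around October 27 (season day 57, days since Sep 1),
#' mean occupancy frequency 0.46, mean relative time investment 0.55, and
#' the reported effect sizes: site quality -4.67 days/SD on return day,
#' +0.82 logit/SD on occupancy frequency, +0.94 logit/SD on relative time
#' investment, occupancy frequency -0.93 days/SD on lay date and return day
#' -0.5 logit/SD on breeding success.
#'
#' @param n_sites_per_subcolony integer vector (length 1 or 2): monitored
#'   sites per subcolony.
#' @param n_seasons number of consecutive non-breeding seasons.
#' @param mean_return_day mean latent return day (days since Sep 1).
#' @param sd_return_day residual SD of the latent return day (days).
#' @param beta_quality_return effect of standardized site quality on return
#'   day (days per SD).
#' @param mean_freq mean occupancy frequency (proportion of surveyed days
#'   occupied, return day to March 31).
#' @param beta_quality_freq site-quality effect on occupancy frequency
#'   (logit units per SD).
#' @param mean_rti mean relative time investment (proportion).
#' @param beta_quality_rti site-quality effect on relative time investment
#'   (logit units per SD).
#' @param mean_laydate mean lay date (ordinal day of the following spring).
#' @param beta_freq_laydate effect of standardized realized occupancy
#'   frequency on lay date (days per SD).
#' @param sd_laydate residual SD of lay date (days).
#' @param intercept_success logit-scale intercept of breeding success.
#' @param beta_return_success effect of standardized realized return day on
#'   breeding success (logit units per SD).
#' @param site_re_sd named numeric: site random-intercept SDs for
#'   \code{return} (days), \code{freq}, \code{rti} (logit), \code{laydate}
#'   (days), \code{success} (logit).
#' @param image_interval image interval in minutes, 15 or 30.
#' @param pairing_prob probability that an occupying bird is joined by its
#'   partner in a given image (gives counts of 2).
#' @param quality_beta_shape \code{c(shape1, shape2)} of the Beta
#'   distribution for site quality (a historic success proportion).
#' @param diel_params list: \code{peak_offset} (h after dawn), \code{rise}
#'   (log-linear rise rate per h), \code{decay} (exponential decline per h),
#'   \code{peak} (probability at the peak), \code{day_length} (h, used when
#'   evaluating the curve outside the simulator).
#' @param seasonal_params list: \code{plateau}, \code{rise_midpoint},
#'   \code{rise_scale} (days), \code{dip_centers}, \code{dip_depths},
#'   \code{dip_widths} (early-December and early-February dips).
#' @param gap_spec data.frame of unscorable intervals with columns
#'   \code{season} (index), \code{subcolony}, \code{start_day},
#'   \code{end_day}; \code{NULL} for none.
#' @param seed integer seed; fully determines the generated colony.
#' @return an object of class \code{cw_truth} (a validated list).
#' @export
simulation_truth <- function(n_sites_per_subcolony = c(27L, 52L),
                             n_seasons = 3L,
                             mean_return_day = 57,
                             sd_return_day = 10,
                             beta_quality_return = -4.67,
                             mean_freq = 0.46,
                             beta_quality_freq = 0.82,
                             mean_rti = 0.55,
                             beta_quality_rti = 0.94,
                             mean_laydate = 130,
                             beta_freq_laydate = -0.93,
                             sd_laydate = 5,
                             intercept_success = 0.85,
                             beta_return_success = -0.5,
                             site_re_sd = c(return = 3, freq = 0.25,
                                            rti = 0.25, laydate = 2,
                                            success = 0.3),
                             image_interval = 15L,
                             pairing_prob = 0.5,
                             quality_beta_shape = c(1.4, 0.6),
                             diel_params = list(peak_offset = 1.5,
                                                rise = 0.5, decay = 0.35,
                                                peak = 0.8, day_length = 12),
                             seasonal_params = list(plateau = 0.5,
                                                    rise_midpoint = 60,
                                                    rise_scale = 12,
                                                    dip_centers = c(92, 154),
                                                    dip_depths = c(0.12, 0.10),
                                                    dip_widths = c(5, 5)),
                             gap_spec = default_gap_spec(),
                             seed = 1L) {
  truth <- list(n_sites_per_subcolony = as.integer(n_sites_per_subcolony),
                n_seasons = as.integer(n_seasons),
                mean_return_day = mean_return_day,
                sd_return_day = sd_return_day,
                beta_quality_return = beta_quality_return,
                mean_freq = mean_freq,
                beta_quality_freq = beta_quality_freq,
                mean_rti = mean_rti,
                beta_quality_rti = beta_quality_rti,
                mean_laydate = mean_laydate,
                beta_freq_laydate = beta_freq_laydate,
                sd_laydate = sd_laydate,
                intercept_success = intercept_success,
                beta_return_success = beta_return_success,
                site_re_sd = site_re_sd,
                image_interval = as.integer(image_interval),
                pairing_prob = pairing_prob,
                quality_beta_shape = quality_beta_shape,
                diel_params = diel_params,
                seasonal_params = seasonal_params,
                gap_spec = gap_spec,
                seed = as.integer(seed))
  class(truth) <- "cw_truth"
  validate_truth(truth)
  truth
}

#' Default camera-outage specification
#'
#' Two short unscorable intervals (fog / battery loss) emulating the
#' sporadic gaps of a real deployment.
#' @return data.frame with columns season, subcolony, start_day, end_day.
#' @export
default_gap_spec <- function() {
  data.frame(season = c(2L, 3L), subcolony = c(2L, 1L),
             start_day = c(100L, 140L), end_day = c(106L, 145L))
}

validate_truth <- function(truth) {
  if (!inherits(truth, "cw_truth"))
    stopf("configuration error: not a 'cw_truth' object")
  ns <- truth$n_sites_per_subcolony
  if (length(ns) < 1 || length(ns) > 2 || any(ns < 1))
    stopf("configuration error: 'n_sites_per_subcolony' must be 1 or 2 positive integers")
  check_positive(truth$n_seasons, "n_seasons")
  check_positive(truth$sd_return_day, "sd_return_day")
  check_positive(truth$sd_laydate, "sd_laydate")
  for (p in c("mean_freq", "mean_rti", "pairing_prob"))
    check_proportion(truth[[p]], p)
  if (!truth$image_interval %in% c(15L, 30L))
    stopf("configuration error: 'image_interval' must be 15 or 30")
  need <- c("return", "freq", "rti", "laydate", "success")
  if (!all(need %in% names(truth$site_re_sd)) || any(truth$site_re_sd < 0))
    stopf("configuration error: 'site_re_sd' must be named (%s) and non-negative",
          paste(need, collapse = ", "))
  if (any(truth$quality_beta_shape <= 0))
    stopf("configuration error: 'quality_beta_shape' must be positive")
  if (truth$mean_return_day < 1 || truth$mean_return_day > SEASON_LENGTH)
    stopf("configuration error: 'mean_return_day' outside the season window")
  validate_gap_spec(truth$gap_spec)
  invisible(truth)
}

validate_gap_spec <- function(gap_spec) {
  if (is.null(gap_spec) || nrow(as.data.frame(gap_spec)) == 0) return(invisible(NULL))
  gs <- as.data.frame(gap_spec)
  need <- c("season", "subcolony", "start_day", "end_day")
  if (!all(need %in% names(gs)))
    stopf("configuration error: gap_spec needs columns %s", paste(need, collapse = ", "))
  if (any(gs$start_day > gs$end_day))
    stopf("configuration error: gap_spec has start_day > end_day")
  if (any(gs$start_day < 1) || any(gs$end_day > SEASON_LENGTH))
    stopf("configuration error: gap_spec interval outside the season window")
  key <- split(gs, interaction(gs$season, gs$subcolony, drop = TRUE))
  for (g in key) {
    if (nrow(g) > 1) {
      g <- g[order(g$start_day), ]
      if (any(g$start_day[-1] <= g$end_day[-nrow(g)]))
        stopf("configuration error: overlapping gap_spec intervals for subcolony %s season %s",
              g$subcolony[1], g$season[1])
    }
  }
  invisible(NULL)
}

#' Diel attendance profile
#'
#' Relative probability that an occupying bird is on its site \code{h} hours
#' after nautical dawn: a log-linear rise to a peak 1-2 h after dawn, then an
#' exponential decline tapering to exactly zero at nautical dusk (and beyond).
#'
#' @param hours_after_dawn non-negative numeric vector.
#' @param diel_params list as in \code{\link{simulation_truth}}; the
#'   dawn-to-dusk span is \code{day_length} hours.
#' @return occupancy probabilities in \code{[0, peak]}.
#' @export
diel_profile <- function(hours_after_dawn,
                         diel_params = simulation_truth()$diel_params) {
  if (any(hours_after_dawn < 0))
    stopf("domain error: 'hours_after_dawn' must be non-negative")
  h0 <- diel_params$peak_offset
  H <- diel_params$day_length
  h <- hours_after_dawn
  p <- ifelse(h < h0,
              diel_params$peak * exp(diel_params$rise * (h - h0)),
              diel_params$peak * exp(-diel_params$decay * (h - h0)) *
                pmax(0, (H - h) / (H - h0)))
  pmax(0, p)
}

#' Seasonal baseline of daily site occupancy
#'
#' Logistic rise to a plateau (about half of sites occupied per day by
#' mid-March) minus two localized Gaussian dips in early December and early
#' February.
#'
#' @param season_day integer day(s) on the season axis (1 = Sep 1).
#' @param seasonal_params list as in \code{\link{simulation_truth}}.
#' @return daily occupancy probabilities.
#' @export
seasonal_curve <- function(season_day,
                           seasonal_params = simulation_truth()$seasonal_params) {
  if (any(season_day < 1 | season_day > SEASON_LENGTH))
    stopf("domain error: season day outside 1..%d", SEASON_LENGTH)
  sp <- seasonal_params
  v <- sp$plateau * plogis((season_day - sp$rise_midpoint) / sp$rise_scale)
  for (k in seq_along(sp$dip_centers)) {
    v <- v - sp$dip_depths[k] *
      exp(-(season_day - sp$dip_centers[k])^2 / (2 * sp$dip_widths[k]^2))
  }
  pmin(1, pmax(0.02, v))
}

#' Remove records falling in declared unscorable intervals
#'
#' Deletes every image-score record inside the given (season, subcolony,
#' day-range) intervals.  Removed days carry no records at all, so the
#' survey ledger treats them as unsurveyed rather than as zero occupancy.
#'
#' @param records image-score data.frame (see \code{\link{simulate_colony}}).
#' @param gap_spec data.frame as in \code{\link{simulation_truth}}; season
#'   may be given as the season index or the season label.
#' @return the filtered records.
#' @export
inject_gaps <- function(records, gap_spec) {
  if (is.null(gap_spec) || nrow(as.data.frame(gap_spec)) == 0) return(records)
  validate_gap_spec(gap_spec)
  gs <- as.data.frame(gap_spec)
  seasons <- sort(unique(records$season))
  day <- date_to_season_day(as.Date(records$date), records$season)
  drop <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(gs))) {
    season_lab <- if (is.numeric(gs$season[i])) seasons[gs$season[i]] else gs$season[i]
    drop <- drop | (records$season == season_lab &
                      records$subcolony == gs$subcolony[i] &
                      day >= gs$start_day[i] & day <= gs$end_day[i])
  }
  records[!drop, , drop = FALSE]
}

#' Generate a synthetic colony
#'
#' Draws image-score records, site qualities, lay dates and breeding
#' outcomes under the supplied ground truth.  Per site and season a latent
#' return day is drawn first; daily occupancy indicators follow a
#' frequency-targeted seasonal shape; image-level presence within occupied
#' days follows the diel profile, calibrated so that the expected relative
#' time investment matches its logit-scale target.  Lay date is Gaussian
#' around the season mean shifted by the realized (standardized) occupancy
#' frequency; success is Bernoulli with logit linear in the realized
#' (standardized) return day.  No presence is generated outside daylight,
#' and declared gap intervals contain no records.
#'
#' @param truth a \code{cw_truth} object from \code{\link{simulation_truth}}.
#' @return an object of class \code{cw_colony}: list with elements
#'   \code{image_scores}, \code{sites}, \code{breeding}, \code{truth},
#'   \code{survey_log} (emitted day/image counts per subcolony-season) and
#'   \code{latents} (the per-site-season generator targets, for parameter-
#'   recovery checks).
#' @export
simulate_colony <- function(truth = simulation_truth()) {
  validate_truth(truth)
  set.seed(substream_seed(truth$seed, "simulate"))

  n_sub <- length(truth$n_sites_per_subcolony)
  seasons <- paste0(2017:(2016 + truth$n_seasons), "/",
                    substr(2018:(2017 + truth$n_seasons), 3, 4))

  ## --- sites and quality -------------------------------------------------
  sites <- do.call(rbind, lapply(seq_len(n_sub), function(sc) {
    n <- truth$n_sites_per_subcolony[sc]
    data.frame(site_id = sprintf("S%d-%02d", sc, seq_len(n)),
               subcolony = sc,
               quality = rbeta(n, truth$quality_beta_shape[1],
                               truth$quality_beta_shape[2]),
               stringsAsFactors = FALSE)
  }))
  n_attempts <- 10L + rbinom(nrow(sites), 26L, 0.8)  # historic attempts behind the quality proportion
  sites$quality <- round(round(sites$quality * n_attempts) / n_attempts, 4)
  sites$quality <- pmin(0.98, pmax(0.02, sites$quality))
  sites$n_attempts <- n_attempts
  # standardize quality within subcolony (constant across seasons)
  z_q <- stats::ave(sites$quality, sites$subcolony,
                    FUN = function(x) (x - mean(x)) / sd(x))

  ## --- per site-season random effects (constant across seasons per site) --
  re <- truth$site_re_sd
  u_ret <- rnorm(nrow(sites), 0, re["return"])
  u_freq <- rnorm(nrow(sites), 0, re["freq"])
  u_rti <- rnorm(nrow(sites), 0, re["rti"])
  u_lay <- rnorm(nrow(sites), 0, re["laydate"])
  u_succ <- rnorm(nrow(sites), 0, re["success"])

  season_days <- seq_len(SEASON_LENGTH)
  shape <- seasonal_curve(season_days, truth$seasonal_params)
  # cumulative mean of the shape from day d to season end, for window scaling
  rev_cummean <- rev(cumsum(rev(shape))) / rev(seq_along(shape))

  all_scores <- vector("list", n_sub * truth$n_seasons)
  latents <- vector("list", n_sub * truth$n_seasons)
  survey_log <- vector("list", n_sub * truth$n_seasons)
  k <- 0L

  for (s in seq_len(truth$n_seasons)) {
    for (sc in seq_len(n_sub)) {
      k <- k + 1L
      idx <- which(sites$subcolony == sc)
      n_site <- length(idx)
      zq <- z_q[idx]

      latent_ret <- round(truth$mean_return_day +
                            truth$beta_quality_return * zq + u_ret[idx] +
                            rnorm(n_site, 0, truth$sd_return_day))
      latent_ret <- pmin(pmax(latent_ret, 20L), 150L)

      f_target <- plogis(qlogis(truth$mean_freq) +
                           truth$beta_quality_freq * zq + u_freq[idx])
      r_target <- plogis(qlogis(truth$mean_rti) +
                           truth$beta_quality_rti * zq + u_rti[idx])

      ## daily occupancy: frequency-targeted seasonal shape
      Z <- matrix(0L, n_site, SEASON_LENGTH)
      for (i in seq_len(n_site)) {
        win <- latent_ret[i]:SEASON_LENGTH
        p <- pmin(1, f_target[i] * shape[win] / rev_cummean[latent_ret[i]])
        Z[i, win] <- rbinom(length(win), 1L, p)
        Z[i, latent_ret[i]] <- 1L  # occupied on the return day by definition
      }

      ## image grids per day
      times_by_day <- lapply(season_days, image_times_for_day,
                             interval = truth$image_interval)
      dl <- daylight_for_days(season_days)
      w_by_day <- lapply(season_days, function(d) {
        t <- times_by_day[[d]]
        if (!length(t)) return(numeric(0))
        dp <- truth$diel_params
        dp$day_length <- (dl$dusk[d] - dl$dawn[d]) / 60
        w <- diel_profile((t - dl$dawn[d]) / 60, dp)
        if (mean(w) <= 0) rep(1, length(t)) else w / mean(w)
      })
      n_img_day <- lengths(times_by_day)

      ## calibrate image-level presence rates so E[RTI] matches r_target.
      ## RTI conditions on the site's occupied days: numerator is the site's
      ## matched images, denominator the subcolony's any-bird images on those
      ## same days; fixed point over the 'any bird present' image profile.
      r_img <- r_target
      occ_days <- lapply(seq_len(n_site), function(i) which(Z[i, ] == 1L))
      for (iter in 1:3) {
        q_by_day_c <- lapply(season_days, function(d) {
          on_d <- which(Z[, d] == 1L)
          if (!length(on_d)) return(numeric(0))
          w <- w_by_day[[d]]
          one_minus <- rep(1, length(w))
          for (i in on_d) one_minus <- one_minus * (1 - r_img[i])^w
          1 - one_minus
        })
        for (i in seq_len(n_site)) {
          qcat <- unlist(q_by_day_c[occ_days[[i]]], use.names = FALSE)
          D <- sum(qcat)                           # denominator on occupied days
          wcat <- unlist(w_by_day[occ_days[[i]]], use.names = FALSE)
          if (!length(wcat)) next
          daycat <- rep(seq_along(occ_days[[i]]),
                        n_img_day[occ_days[[i]]])
          # an occupied day with no drawn presence gets one forced image at
          # the diel peak; discount the expected forced count from the target
          p0 <- 1 - (1 - r_img[i])^wcat
          forced <- sum(exp(rowsum(log1p(-p0), daycat)))
          # delta-method correction for E[num/den] < E[num]/E[den]: the
          # site's own presences sit in the shared denominator, so
          # Cov(N, D) = sum p(1-q) and Var(D) = sum q(1-q) compress the
          # realized ratio; retarget the mean ratio accordingly
          muN <- sum(p0)
          if (muN > 0 && D > 0) {
            fcorr <- 1 - sum(p0 * (1 - qcat)) / (muN * D) +
              sum(qcat * (1 - qcat)) / D^2
            fcorr <- min(1, max(0.5, fcorr))
          } else fcorr <- 1
          target_num <- (r_target[i] / fcorr) * D - forced
          if (target_num <= 0) { r_img[i] <- 1e-6; next }
          # presence per image follows p = 1 - (1 - rho)^w: diel-shaped for
          # small rho, saturating to 1 without a hard cap for high-investment
          # sites; solve rho so the expected numerator hits the target
          lo <- 0; hi <- 1 - 1e-9
          if (sum(1 - (1 - hi)^wcat) <= target_num) { r_img[i] <- hi; next }
          for (b in 1:30) {
            mid <- (lo + hi) / 2
            if (sum(1 - (1 - mid)^wcat) < target_num) lo <- mid else hi <- mid
          }
          r_img[i] <- (lo + hi) / 2
        }
      }

      ## draw image-level presence
      day_vec <- rep(season_days, n_img_day)
      time_vec <- unlist(times_by_day, use.names = FALSE)
      w_vec <- unlist(w_by_day, use.names = FALSE)
      n_img <- length(day_vec)
      score_mat <- matrix(0L, n_site, n_img)
      for (i in seq_len(n_site)) {
        occ <- Z[i, day_vec] == 1L
        if (!any(occ)) next
        p <- 1 - (1 - r_img[i])^w_vec[occ]
        x <- as.integer(runif(sum(occ)) < p)
        score_mat[i, occ] <- x
        # ensure every occupied day shows at least one presence (at the diel peak)
        hit_days <- unique(day_vec[occ][x == 1L])
        miss <- setdiff(occ_days[[i]], hit_days)
        for (d in miss) {
          j <- which(day_vec == d)
          score_mat[i, j[which.max(w_vec[j])]] <- 1L
        }
      }
      # second bird: independent thinning of first-bird presence
      pres <- score_mat == 1L
      score_mat[pres] <- score_mat[pres] +
        as.integer(runif(sum(pres)) < truth$pairing_prob)

      ## realized (biological) occupancy summaries, pre-gap
      real_ret <- apply(Z, 1, function(z) which(z == 1L)[1])
      real_freq <- vapply(seq_len(n_site), function(i)
        mean(Z[i, real_ret[i]:SEASON_LENGTH]), 0)

      sl <- data.frame(season = seasons[s], subcolony = sc,
                       n_days = SEASON_LENGTH, n_images = n_img,
                       stringsAsFactors = FALSE)

      scores <- data.frame(
        subcolony = sc,
        site_id = rep(sites$site_id[idx], each = n_img),
        season = seasons[s],
        date = rep(season_day_to_date(day_vec, seasons[s]), n_site),
        time = rep(time_vec, n_site),
        count = as.integer(t(score_mat)),
        stringsAsFactors = FALSE)

      latents[[k]] <- data.frame(
        site_id = sites$site_id[idx], subcolony = sc, season = seasons[s],
        quality = sites$quality[idx], z_quality = zq,
        latent_return = latent_ret, realized_return = real_ret,
        f_target = f_target, realized_freq = real_freq, r_target = r_target,
        stringsAsFactors = FALSE)
      all_scores[[k]] <- scores
      survey_log[[k]] <- sl
    }
  }

  image_scores <- do.call(rbind, all_scores)
  latents <- do.call(rbind, latents)
  survey_log <- do.call(rbind, survey_log)

  ## apply declared camera gaps (observation process only)
  image_scores <- inject_gaps(image_scores, truth$gap_spec)
  # recompute emitted counts after gaps
  agg <- aggregate(list(n_images = image_scores$time),
                   by = list(season = image_scores$season,
                             subcolony = image_scores$subcolony),
                   FUN = length)
  nd <- aggregate(list(n_days = image_scores$date),
                  by = list(season = image_scores$season,
                            subcolony = image_scores$subcolony),
                  FUN = function(x) length(unique(x)))
  survey_log <- merge(nd, agg, by = c("season", "subcolony"))
  n_per_site <- vapply(split(image_scores$site_id, image_scores$subcolony),
                       function(x) length(unique(x)), 0L)
  survey_log$n_sites <- n_per_site[as.character(survey_log$subcolony)]
  survey_log$n_images <- survey_log$n_images / survey_log$n_sites

  ## breeding outcomes from the realized (pre-gap) behavior
  grp <- interaction(latents$subcolony, latents$season, drop = TRUE)
  z_ret <- stats::ave(latents$realized_return, grp,
                      FUN = function(x) (x - mean(x)) / sd(x))
  z_freq <- stats::ave(latents$realized_freq, grp,
                       FUN = function(x) (x - mean(x)) / sd(x))
  site_row <- match(latents$site_id, sites$site_id)
  lay <- round(truth$mean_laydate + truth$beta_freq_laydate * z_freq +
                 u_lay[site_row] + rnorm(nrow(latents), 0, truth$sd_laydate))
  p_succ <- plogis(truth$intercept_success +
                     truth$beta_return_success * z_ret + u_succ[site_row])
  success <- rbinom(nrow(latents), 1L, p_succ)
  breeding <- data.frame(site_id = latents$site_id, season = latents$season,
                         lay_date = lay, success = success,
                         stringsAsFactors = FALSE)

  out <- list(image_scores = image_scores, sites = sites,
              breeding = breeding, truth = truth,
              survey_log = survey_log, latents = latents)
  class(out) <- "cw_colony"
  out
}

#' @export
print.cw_colony <- function(x, ...) {
  cat("Synthetic colony:",
      nrow(x$sites), "sites,",
      length(unique(x$image_scores$season)), "seasons,",
      nrow(x$image_scores), "image-score records\n")
  invisible(x)
}
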