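# Occupancy metrics from image-score records.
#
# Three measures per site and season (each under a presence filter):
#   return date  - first survey day with a matching presence;
#   occupancy frequency - proportion of survey days occupied from the
#       return day to March 31;
#   relative time investment (RTI) - images with the site occupied divided
#       by images with any bird present in the subcolony, summed over
#       survey days from the site's return day.
# Days without any scorable image (camera gaps) are excluded from every
# denominator; they are never scored as absence.

match_presence <- function(count, presence_filter) {
  switch(presence_filter,
         any = count >= 1L,
         pair = count == 2L,
         single = count == 1L,
         stopf("unknown presence filter '%s'", presence_filter))
}

# normalize a record table: add season_day, validate counts and duplicates
prepare_records <- function(records) {
  need <- c("subcolony", "site_id", "season", "date", "time", "count")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopf("data error: image-score table lacks column(s) %s",
          paste(miss, collapse = ", "))
  if (!all(records$count %in% 0:2)) {
    bad <- which(!(records$count %in% 0:2))
    stopf("data error: count outside {0,1,2} at row(s) %s",
          paste(head(bad, 5), collapse = ", "))
  }
  records$season_day <- date_to_season_day(as.Date(records$date), records$season)
  site_f <- as.integer(factor(records$site_id))
  sea_f <- as.integer(factor(records$season))
  key <- ((site_f - 1) * max(sea_f) + (sea_f - 1)) *
    (SEASON_LENGTH + 1) * 1440 + records$season_day * 1440 + records$time
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))
    stopf("data error: duplicate (site, timestamp) records at row(s) %s",
          paste(head(bad, 5), collapse = ", "))
  }
  records
}

#' Build the survey-day ledger
#'
#' A day counts as a survey day for a subcolony-season iff at least one
#' scorable image exists for it.  Declared gap days are asserted to carry no
#' records.
#'
#' @param records image-score data.frame (columns subcolony, site_id,
#'   season, date, time, count).
#' @param declared_gaps optional gap_spec data.frame (see
#'   \code{\link{simulation_truth}}); used only to cross-check that gap days
#'   are empty.
#' @return list with \code{days} (subcolony, season, season_day, n_images)
#'   and \code{site_days} (per site-day scored flag).
#' @export
build_survey_ledger <- function(records, declared_gaps = NULL) {
  records <- prepare_records(records)
  img_key <- paste(records$subcolony, records$season, records$season_day,
                   records$time)
  first <- !duplicated(img_key)
  days <- aggregate(list(n_images = records$time[first]),
                    by = list(subcolony = records$subcolony[first],
                              season = records$season[first],
                              season_day = records$season_day[first]),
                    FUN = length)
  days <- days[order(days$subcolony, days$season, days$season_day), ]
  rownames(days) <- NULL
  sd_key <- paste(records$site_id, records$season, records$season_day)
  firsts <- !duplicated(sd_key)
  site_days <- data.frame(subcolony = records$subcolony[firsts],
                          site_id = records$site_id[firsts],
                          season = records$season[firsts],
                          season_day = records$season_day[firsts],
                          scored = TRUE, stringsAsFactors = FALSE)
  if (!is.null(declared_gaps) && nrow(as.data.frame(declared_gaps))) {
    gs <- as.data.frame(declared_gaps)
    seasons <- sort(unique(records$season))
    for (i in seq_len(nrow(gs))) {
      lab <- if (is.numeric(gs$season[i])) seasons[gs$season[i]] else gs$season[i]
      inside <- days$season == lab & days$subcolony == gs$subcolony[i] &
        days$season_day >= gs$start_day[i] & days$season_day <= gs$end_day[i]
      if (any(inside))
        stopf("data error: records found inside declared gap (subcolony %s, season %s)",
              gs$subcolony[i], lab)
    }
  }
  list(days = days, site_days = site_days)
}

#' First day a site is occupied in a season
#'
#' @param records image-score data.frame.
#' @param site site_id.
#' @param season season label.
#' @param presence_filter "any" (1 or 2 birds), "pair" (exactly 2) or
#'   "single" (exactly 1).
#' @return the season day of first matching occupancy, or \code{NA} if the
#'   site is never occupied in that season.
#' @export
return_date <- function(records, site, season, presence_filter = "any") {
  records <- prepare_records(records)
  if (!site %in% records$site_id) stopf("unknown site '%s'", site)
  r <- records[records$site_id == site & records$season == season, ]
  hit <- match_presence(r$count, presence_filter)
  if (!any(hit)) return(NA_integer_)
  min(r$season_day[hit])
}

#' Occupancy frequency of one site-season
#'
#' Proportion of survey days, from the return day to March 31, on which the
#' site shows a matching presence.
#'
#' @inheritParams return_date
#' @return list with \code{num}, \code{den}, \code{value}.
#' @export
occupancy_frequency <- function(records, site, season, presence_filter = "any") {
  m <- compute_metrics(records, presence_filter = presence_filter)
  row <- m[m$site_id == site & m$season == season, ]
  if (!nrow(row)) stopf("unknown site '%s'", site)
  if (is.na(row$return_day))
    stopf("undefined metric: site '%s' never occupied in %s", site, season)
  if (row$occ_freq_den == 0)
    stopf("undefined metric: no survey days in window for site '%s'", site)
  list(num = row$occ_freq_num, den = row$occ_freq_den, value = row$occ_freq)
}

#' Relative time investment of one site-season
#'
#' Images with a matching presence at the site divided by images with at
#' least one bird anywhere in the subcolony, both summed over survey days
#' from the site's return day.  A per-day series is also returned.
#'
#' @inheritParams return_date
#' @param rti_days \code{"occupied"} (ratio of sums over the site's occupied
#'   days from its return day; default), \code{"window"} (all survey days
#'   from the return day) or \code{"season"}.
#' @return list with \code{num}, \code{den}, \code{value}, \code{per_day}
#'   (data.frame season_day, num, den over the survey days from return).
#' @export
relative_time_investment <- function(records, site, season,
                                     presence_filter = "any",
                                     rti_days = "occupied") {
  records <- prepare_records(records)
  if (!site %in% records$site_id) stopf("unknown site '%s'", site)
  sc <- records$subcolony[match(site, records$site_id)]
  r <- records[records$subcolony == sc & records$season == season, ]
  ret <- if (rti_days == "season") 1L else
    return_date(r, site, season, presence_filter)
  if (is.na(ret))
    stopf("undefined metric: site '%s' never occupied in %s", site, season)
  r <- r[r$season_day >= ret, ]
  img_key <- paste(r$season_day, r$time)
  any_bird <- tapply(r$count >= 1L, img_key, any)
  day_of_img <- as.integer(vapply(strsplit(names(any_bird), " "),
                                  `[`, "", 1))
  den_day <- tapply(as.integer(any_bird), day_of_img, sum)
  rs <- r[r$site_id == site, ]
  num_day <- tapply(as.integer(match_presence(rs$count, presence_filter)),
                    rs$season_day, sum)
  days <- sort(unique(day_of_img))
  per_day <- data.frame(season_day = days,
                        num = as.integer(num_day[as.character(days)]),
                        den = as.integer(den_day[as.character(days)]))
  per_day$num[is.na(per_day$num)] <- 0L
  use <- if (rti_days == "occupied") per_day$num > 0L else rep(TRUE, nrow(per_day))
  den <- sum(per_day$den[use]); num <- sum(per_day$num[use])
  if (den == 0) stopf("undefined metric: RTI denominator is zero for '%s'", site)
  list(num = num, den = den, value = num / den, per_day = per_day)
}

#' Occupancy metrics for every site-season
#'
#' Vectorized driver computing return day, occupancy frequency and relative
#' time investment for all sites and seasons under one presence filter.
#' Sites never occupied in a season get \code{NA} return day and zero
#' numerators; their count is reported via the \code{n_never_occupied}
#' attribute.
#'
#' @param records image-score data.frame.
#' @param declared_gaps optional gap_spec, cross-checked via the ledger.
#' @param presence_filter "any", "pair" or "single".
#' @param rti_days day set over which the RTI ratio of sums runs:
#'   \code{"occupied"} (the site's occupied days from its return day; the
#'   daily-duration reading, default), \code{"window"} (every survey day
#'   from the return day) or \code{"season"} (all survey days).
#' @return data.frame with one row per site x season: return_day,
#'   occ_freq_num/den, occ_freq, rti_num/den, rti, presence_filter.
#' @export
compute_metrics <- function(records, declared_gaps = NULL,
                            presence_filter = "any", rti_days = "occupied") {
  records <- prepare_records(records)
  if (!is.null(declared_gaps)) build_survey_ledger(records, declared_gaps)

  sea_f <- factor(records$season)
  sub_f <- factor(records$subcolony)
  site_f <- factor(records$site_id)
  ss_code <- (as.integer(sea_f) - 1L) * nlevels(sub_f) + as.integer(sub_f)
  uss_code <- sort(unique(ss_code))
  ss_i <- match(ss_code, uss_code)
  sisea_code <- (as.integer(sea_f) - 1L) * nlevels(site_f) + as.integer(site_f)
  usisea_code <- sort(unique(sisea_code))
  sisea_i <- match(sisea_code, usisea_code)
  day <- records$season_day
  L <- SEASON_LENGTH
  n_ss <- length(uss_code); n_sisea <- length(usisea_code)
  match_vec <- match_presence(records$count, presence_filter)

  ## per subcolony-season x day: survey day flag and any-bird image count
  day_id <- (day - 1L) * n_ss + ss_i               # day-major cell id
  img_id <- as.numeric(day_id) * 1440 + records$time
  uimg <- unique(img_id)
  img_i <- match(img_id, uimg)
  present_by_img <- tabulate(img_i[records$count >= 1L], length(uimg))
  u_day <- as.integer(floor((uimg - uimg %% 1440) / 1440))  # day_id per image
  a_mat <- matrix(0L, n_ss, L)       # any-bird images per day (ss x day)
  s_mat <- matrix(0L, n_ss, L)       # scorable images per day
  a_mat[] <- tabulate(u_day[present_by_img > 0L], n_ss * L)
  s_mat[] <- tabulate(u_day, n_ss * L)
  survey <- s_mat > 0L

  ## per site-season x day: matched day-presence and matched image counts
  sd_cell <- (day - 1L) * n_sisea + sisea_i
  p_mat <- matrix(0L, n_sisea, L)
  p_mat[] <- tabulate(sd_cell[match_vec], n_sisea * L)  # matched images/day

  ## map each site-season to its subcolony-season
  first_sisea <- match(usisea_code, sisea_code)
  sisea_ss <- ss_i[first_sisea]
  site_of <- as.character(site_f[first_sisea])
  season_of <- as.character(sea_f[first_sisea])
  subcol_of <- records$subcolony[first_sisea]

  ret <- apply(p_mat > 0L, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)

  # reverse cumulative sums along days for windowed totals
  revcum <- function(m) t(apply(m, 1, function(x) rev(cumsum(rev(x)))))
  surv_cum <- revcum(survey * 1L)
  a_cum <- revcum(a_mat)
  occ_cum <- revcum((p_mat > 0L) * 1L)
  img_cum <- revcum(p_mat)

  n <- n_sisea
  occ_num <- occ_den <- rti_num <- rti_den <- integer(n)
  for (i in seq_len(n)) {
    if (is.na(ret[i])) next
    occ_num[i] <- occ_cum[i, ret[i]]
    occ_den[i] <- surv_cum[sisea_ss[i], ret[i]]
    if (rti_days == "occupied") {
      od <- which(p_mat[i, ] > 0L)               # all >= ret by construction
      rti_num[i] <- sum(p_mat[i, od])
      rti_den[i] <- sum(a_mat[sisea_ss[i], od])
    } else {
      w0 <- if (rti_days == "window") ret[i] else 1L
      rti_num[i] <- img_cum[i, w0]
      rti_den[i] <- a_cum[sisea_ss[i], w0]
    }
  }

  out <- data.frame(site_id = site_of, subcolony = subcol_of,
                    season = season_of, presence_filter = presence_filter,
                    return_day = ret,
                    occ_freq_num = occ_num, occ_freq_den = occ_den,
                    occ_freq = ifelse(occ_den > 0, occ_num / occ_den, NA_real_),
                    rti_num = rti_num, rti_den = rti_den,
                    rti = ifelse(rti_den > 0, rti_num / rti_den, NA_real_),
                    stringsAsFactors = FALSE)
  stopifnot(all(out$occ_freq_num <= out$occ_freq_den),
            all(out$rti_num <= out$rti_den))
  out <- out[order(out$subcolony, out$season, out$site_id), ]
  rownames(out) <- NULL
  attr(out, "n_never_occupied") <- sum(is.na(ret))
  out
}

#' Standardize values within groups
#'
#' Subtracts the group mean and divides by the group sample SD (n-1
#' denominator), the convention used before all model fitting (groups are
#' subcolony x season).  The mapping is retained so effect sizes can be
#' back-transformed to natural units.
#'
#' @param values numeric vector.
#' @param groups grouping vector (same length).
#' @return data.frame with raw, z, group, group_mean, group_sd.
#' @export
standardize <- function(values, groups) {
  groups <- as.character(groups)
  for (g in unique(groups)) {
    v <- values[groups == g]
    if (length(v) < 2 || length(unique(v)) < 2 || sd(v) == 0)
      stopf("degenerate group '%s': need >= 2 distinct values to standardize", g)
  }
  gm <- stats::ave(values, groups, FUN = mean)
  gs <- stats::ave(values, groups, FUN = sd)
  data.frame(raw = values, z = (values - gm) / gs, group = groups,
             group_mean = gm, group_sd = gs, stringsAsFactors = FALSE)
}

#' Colony-level daily and hourly occupancy summaries
#'
#' Daily: per subcolony-season-day, the share of monitored sites with at
#' least one occupied image.  Hourly: per whole hour after nautical dawn,
#' the mean (and SD) across days of the share of sites occupied in that
#' hour, overall and by month.
#'
#' @param records image-score data.frame.
#' @return list with \code{daily} and \code{hourly} data.frames.
#' @export
colony_summaries <- function(records) {
  records <- prepare_records(records)
  L <- SEASON_LENGTH
  ss <- paste(records$subcolony, records$season, sep = "\r")
  uss <- sort(unique(ss))
  ss_i <- match(ss, uss)
  usite <- sort(unique(records$site_id))
  site_i <- match(records$site_id, usite)
  n_sites_ss <- vapply(split(site_i, ss_i), function(x) length(unique(x)), 0L)
  occ <- records$count >= 1L

  ## daily: share of monitored sites with >= 1 occupied image
  day_id <- (ss_i - 1L) * L + records$season_day
  sd_id <- day_id * (length(usite) + 1) + site_i
  occ_sd <- rowsum(as.integer(occ), sd_id) > 0L
  usd <- sort(unique(sd_id))
  occ_day <- rowsum(as.integer(occ_sd[, 1]),
                    floor(usd / (length(usite) + 1)))
  udid <- as.integer(rownames(occ_day))
  ss_of <- (udid - 1L) %/% L + 1L
  parts <- strsplit(uss[ss_of], "\r")
  daily <- data.frame(subcolony = vapply(parts, `[`, "", 1),
                      season = vapply(parts, `[`, "", 2),
                      season_day = udid - (ss_of - 1L) * L,
                      n_occupied = occ_day[, 1],
                      n_sites = as.integer(n_sites_ss[ss_of]),
                      stringsAsFactors = FALSE)
  daily$prop_occupied <- daily$n_occupied / daily$n_sites
  daily <- daily[order(daily$subcolony, daily$season, daily$season_day), ]
  rownames(daily) <- NULL

  ## hourly: share of sites occupied per whole hour after dawn
  dl <- daylight_for_days(records$season_day)
  hour_bin <- pmax(0L, as.integer(floor((records$time - dl$dawn) / 60)))
  mon <- as.integer(substr(season_day_to_month_day(records$season_day), 1, 2))
  shd_id <- (sd_id * 24 + hour_bin)
  occ_shd <- rowsum(as.integer(occ), shd_id) > 0L
  ushd <- sort(unique(shd_id))
  hr <- ushd %% 24
  sdid2 <- floor(ushd / 24)
  dayid2 <- floor(sdid2 / (length(usite) + 1))
  ss2 <- (dayid2 - 1L) %/% L + 1L
  day2 <- dayid2 - (ss2 - 1L) * L
  mon2 <- as.integer(substr(season_day_to_month_day(day2), 1, 2))
  # share of sites occupied for each (subcolony-season-day, hour)
  cell <- paste(dayid2, hr)
  ucell <- sort(unique(cell))
  cell_first <- match(ucell, cell)
  sh <- data.frame(hour = hr[cell_first], month = mon2[cell_first],
                   share = rowsum(as.integer(occ_shd[, 1]), cell)[, 1] /
                     n_sites_ss[ss2[cell_first]])
  agg2 <- function(d, lab) {
    a <- aggregate(share ~ hour, data = d,
                   FUN = function(x) c(mean = mean(x), sd = sd(x)))
    data.frame(month = lab, hour = a$hour, mean_share = a$share[, "mean"],
               sd_share = a$share[, "sd"], stringsAsFactors = FALSE)
  }
  hourly <- do.call(rbind, c(list(agg2(sh, "all")),
                             lapply(split(sh, month.abb[sh$month]),
                                    function(d) agg2(d, month.abb[d$month[1]]))))
  rownames(hourly) <- NULL
  list(daily = daily, hourly = hourly)
}
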