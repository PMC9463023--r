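# Internal helpers: the season-day axis, seed substreams, small assertions.
#
# The season runs Sep 1 .. Mar 31 and crosses the calendar-year boundary, so
# all internal bookkeeping uses a single monotone axis: season day 1 = Sep 1.
# Files use ISO calendar dates; conversion happens at the IO boundary.

SEASON_LENGTH <- 212L  # Sep 1 .. Mar 31 (non-leap February)

#' Convert a calendar date to the internal season-day axis
#'
#' Season day 1 is September 1 of the season's starting year; the axis runs
#' monotonically to March 31 (day 212).  A season is identified by a label
#' such as \code{"2017/18"}, meaning Sep 2017 -- Mar 2018.
#'
#' @param date a \code{Date} vector.
#' @param season season label(s), e.g. \code{"2017/18"}.
#' @return integer season days.
#' @export
date_to_season_day <- function(date, season) {
  us <- unique(season)
  origins <- as.Date(paste0(substr(us, 1, 4), "-08-31"))
  as.integer(date - origins[match(season, us)])
}

#' Convert season days back to calendar dates
#'
#' @param season_day integer day(s) on the internal axis (1 = Sep 1).
#' @param season season label(s), e.g. \code{"2017/18"}.
#' @return a \code{Date} vector.
#' @export
season_day_to_date <- function(season_day, season) {
  us <- unique(season)
  origins <- as.Date(paste0(substr(us, 1, 4), "-08-31"))
  origins[match(season, us)] + season_day
}

# month-day string ("MM-DD") for a season day; used to key the daylight table
season_day_to_month_day <- function(season_day) {
  format(as.Date("2018-08-31") + season_day, "%m-%d")
}

# Deterministic per-stage seeds derived from one root seed.  Keeps every
# substream below 2^31 and distinct across stage names.
substream_seed <- function(root_seed, name) {
  h <- sum(as.integer(charToRaw(name)) * seq_along(charToRaw(name)))
  as.integer((as.numeric(root_seed) * 7919 + h * 104729) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stopf("configuration error: '%s' must be a positive number", name)
  invisible(x)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0 || x >= 1)
    stopf("configuration error: '%s' must lie strictly in (0, 1)", name)
  invisible(x)
}
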