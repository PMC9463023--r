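# Daylight lookup: nautical dawn/dusk by month-day at the study latitude
# (56 N), shipped as a precomputed plain-text fixture.  Attendance is only
# scorable between dawn and dusk; no overnight occupancy exists.

.daylight_env <- new.env(parent = emptyenv())

#' Nautical dawn/dusk table for the non-breeding season
#'
#' Returns the packaged dawn/dusk table (minutes since midnight) for each
#' month-day from September 1 to March 31 at 56 degrees N.  Used by the
#' simulator to place image timestamps and by summaries binning occupancy by
#' hour after dawn.
#'
#' @return data.frame with columns \code{month_day} ("MM-DD"),
#'   \code{dawn_min}, \code{dusk_min}.
#' @export
daylight_table <- function() {
  if (is.null(.daylight_env$tab)) {
    path <- system.file("extdata", "daylight_56N.csv", package = "colonywatch")
    if (path == "") path <- file.path("inst", "extdata", "daylight_56N.csv")
    .daylight_env$tab <- read.csv(path, stringsAsFactors = FALSE)
  }
  .daylight_env$tab
}

# dawn/dusk (minutes) for a vector of season days
daylight_for_days <- function(season_day) {
  tab <- daylight_table()
  idx <- match(season_day_to_month_day(season_day), tab$month_day)
  if (anyNA(idx)) stopf("season day out of range 1..%d", SEASON_LENGTH)
  list(dawn = tab$dawn_min[idx], dusk = tab$dusk_min[idx])
}

# clock-aligned image times (minutes since midnight) within daylight
image_times_for_day <- function(season_day, interval) {
  dl <- daylight_for_days(season_day)
  times <- seq(0L, 1439L, by = as.integer(interval))
  times[times >= dl$dawn & times <= dl$dusk]
}
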