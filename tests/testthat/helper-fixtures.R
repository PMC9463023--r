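# Shared fixtures: a small fast synthetic colony and the hand-scored
# 5-site x 10-day table with hand-computed expected metrics.

# small, quick truth for unit tests (one subcolony unless asked otherwise)
small_truth <- function(seed = 101, ...) {
  defaults <- list(n_sites_per_subcolony = c(8L, 6L), n_seasons = 2L,
                   image_interval = 30L, gap_spec = NULL, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_truth, args)
}

.fixture_env <- new.env()
small_colony <- function() {
  if (is.null(.fixture_env$colony))
    .fixture_env$colony <- simulate_colony(small_truth())
  .fixture_env$colony
}

# Hand-scored fixture: subcolony 1, season "2019/20", season days 50..59
# (day 53 is a camera gap: no records), two images per day (540, 600 min).
# Counts per site per (day, image):
#   A occupies every image with a pair; C is never occupied.
hand_fixture <- function() {
  days <- c(50:52, 54:59)
  counts <- list(
    A = rbind(c(2,2), c(2,2), c(2,2), c(2,2), c(2,2), c(2,2), c(2,2), c(2,2), c(2,2)),
    B = rbind(c(0,0), c(0,0), c(0,1), c(1,1), c(1,0), c(0,0), c(1,0), c(0,0), c(1,1)),
    C = rbind(c(0,0), c(0,0), c(0,0), c(0,0), c(0,0), c(0,0), c(0,0), c(0,0), c(0,0)),
    D = rbind(c(0,0), c(0,0), c(0,0), c(0,0), c(2,0), c(0,0), c(0,0), c(1,2), c(0,0)),
    E = rbind(c(1,0), c(0,0), c(0,0), c(0,2), c(0,0), c(1,1), c(0,0), c(0,0), c(2,1)))
  rows <- list()
  for (s in names(counts)) {
    for (di in seq_along(days)) {
      rows[[length(rows) + 1]] <- data.frame(
        subcolony = 1L, site_id = s, season = "2019/20",
        date = season_day_to_date(days[di], "2019/20"),
        time = c(540L, 600L), count = counts[[s]][di, ],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# hand-computed expected metrics for the fixture (integer num/den), by filter
hand_expected <- function() {
  list(
    any = data.frame(
      site_id = c("A", "B", "C", "D", "E"),
      return_day = c(50L, 52L, NA, 55L, 50L),
      occ_freq_num = c(9L, 5L, 0L, 2L, 4L),
      occ_freq_den = c(9L, 7L, 0L, 5L, 9L),
      rti_num = c(18L, 7L, 0L, 3L, 6L),
      rti_den = c(18L, 10L, 0L, 4L, 8L),
      stringsAsFactors = FALSE),
    pair = data.frame(
      site_id = c("A", "B", "C", "D", "E"),
      return_day = c(50L, NA, NA, 55L, 54L),
      occ_freq_num = c(9L, 0L, 0L, 2L, 2L),
      occ_freq_den = c(9L, 0L, 0L, 5L, 6L),
      rti_num = c(18L, 0L, 0L, 2L, 2L),
      rti_den = c(18L, 0L, 0L, 4L, 4L),
      stringsAsFactors = FALSE))
}

# simple mixed-model data generator for selection/recovery checks
make_lmm_data <- function(n_groups = 30, per_group = 4, beta = c(1, 0, 0),
                          sd_group = 0.5, sd_resid = 1, seed = 1) {
  set.seed(seed)
  n <- n_groups * per_group
  g <- rep(seq_len(n_groups), each = per_group)
  X <- matrix(rnorm(n * 3), n, 3)
  y <- as.vector(X %*% beta) + rnorm(n_groups, 0, sd_group)[g] +
    rnorm(n, 0, sd_resid)
  data.frame(y = y, x1 = X[, 1], x2 = X[, 2], x3 = X[, 3],
             site_id = factor(g))
}
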