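test_that("diel profile peaks 1-2 h after dawn and vanishes at dusk", {
  dp <- simulation_truth()$diel_params
  expect_lt(diel_profile(0, dp), diel_profile(1.5, dp))
  expect_equal(diel_profile(dp$day_length, dp), 0)
  expect_equal(diel_profile(dp$day_length + 3, dp), 0)
  h <- seq(0, dp$day_length, by = 0.01)
  peak_h <- h[which.max(diel_profile(h, dp))]
  expect_gte(peak_h, 1)
  expect_lte(peak_h, 2)
  expect_error(diel_profile(-0.5, dp), "non-negative")
})

test_that("seasonal curve rises to ~0.5 by mid-March with localized dips", {
  sp <- simulation_truth()$seasonal_params
  expect_equal(seasonal_curve(196, sp), 0.5, tolerance = 0.01)
  # frozen reference values from independent evaluation of the formula
  expect_equal(seasonal_curve(c(57, 92, 120, 154, 196), sp),
               c(0.2189117496, 0.3475154154, 0.4966535559, 0.3998019274,
                 0.4999940164), tolerance = 1e-9)
  sp0 <- sp
  sp0$dip_depths <- c(0, 0)
  v <- seasonal_curve(1:212, sp0)
  expect_true(all(diff(v) >= 0))
  expect_error(seasonal_curve(0, sp), "domain error")
  expect_error(seasonal_curve(213, sp), "domain error")
})

test_that("generated colonies respect the structural contracts", {
  col <- small_colony()
  sc <- col$image_scores
  expect_true(all(sc$count %in% 0:2))
  # every image-score site and breeding site appears in the site table
  expect_true(all(sc$site_id %in% col$sites$site_id))
  expect_true(all(col$breeding$site_id %in% col$sites$site_id))
  # no record outside daylight
  day <- date_to_season_day(as.Date(sc$date), sc$season)
  dl <- colonywatch:::daylight_for_days(day)
  expect_true(all(sc$time >= dl$dawn & sc$time <= dl$dusk))
  # site quality is a proportion
  expect_true(all(col$sites$quality > 0 & col$sites$quality < 1))
})

test_that("a seed fully determines the generated colony", {
  a <- simulate_colony(small_truth(seed = 77))
  b <- simulate_colony(small_truth(seed = 77))
  expect_identical(a$image_scores, b$image_scores)
  expect_identical(a$breeding, b$breeding)
  c2 <- simulate_colony(small_truth(seed = 78))
  expect_false(identical(a$image_scores$count, c2$image_scores$count))
})

test_that("with null effects the metrics are independent of quality and hit their means", {
  truth <- small_truth(seed = 303,
                       n_sites_per_subcolony = c(40L, 40L), n_seasons = 2L,
                       beta_quality_return = 0, beta_quality_freq = 0,
                       beta_quality_rti = 0, beta_freq_laydate = 0,
                       beta_return_success = 0,
                       site_re_sd = c(return = 0, freq = 0, rti = 0,
                                      laydate = 0, success = 0))
  col <- simulate_colony(truth)
  m <- compute_metrics(col$image_scores)
  mm <- merge(m, col$sites, by = "site_id")
  expect_lt(abs(cor(mm$return_day, mm$quality)), 0.25)
  n <- nrow(mm)
  # realized means within 3 Monte-Carlo SEs of the configured means
  expect_lt(abs(mean(mm$return_day) - truth$mean_return_day),
            3 * sd(mm$return_day) / sqrt(n) + 1)  # +1 day: integer rounding
  expect_lt(abs(mean(mm$occ_freq) - truth$mean_freq),
            3 * sd(mm$occ_freq) / sqrt(n))
  expect_lt(abs(mean(mm$rti) - truth$mean_rti),
            3 * sd(mm$rti) / sqrt(n))
})

test_that("gap injection removes exactly the declared intervals", {
  col <- small_colony()
  sc <- col$image_scores
  expect_identical(inject_gaps(sc, NULL), sc)
  gs <- data.frame(season = 1L, subcolony = 1L, start_day = 80L,
                   end_day = 80L)
  out <- inject_gaps(sc, gs)
  day <- date_to_season_day(as.Date(out$date), out$season)
  season1 <- sort(unique(sc$season))[1]
  expect_false(any(out$season == season1 & out$subcolony == 1 & day == 80))
  # untouched elsewhere
  expect_equal(nrow(out[out$subcolony == 2, ]), nrow(sc[sc$subcolony == 2, ]))
  # removed day is unsurveyed, not zero-occupancy
  led <- build_survey_ledger(out)
  d1 <- led$days[led$days$season == season1 & led$days$subcolony == 1, ]
  expect_false(80 %in% d1$season_day)
  bad <- data.frame(season = c(1L, 1L), subcolony = c(1L, 1L),
                    start_day = c(10L, 12L), end_day = c(14L, 20L))
  expect_error(inject_gaps(sc, bad), "overlapping")
})

test_that("invalid truth configurations are rejected by field name", {
  expect_error(simulation_truth(mean_freq = 1.2), "mean_freq")
  expect_error(simulation_truth(image_interval = 10), "image_interval")
  expect_error(simulation_truth(sd_return_day = -1), "sd_return_day")
  expect_error(simulation_truth(site_re_sd = c(return = 1)), "site_re_sd")
})
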