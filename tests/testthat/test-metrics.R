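test_that("hand-scored fixture reproduces hand-computed metrics exactly", {
  recs <- hand_fixture()
  for (fl in c("any", "pair")) {
    m <- compute_metrics(recs, presence_filter = fl)
    exp_tab <- hand_expected()[[fl]]
    m <- m[match(exp_tab$site_id, m$site_id), ]
    expect_equal(m$return_day, exp_tab$return_day)
    expect_identical(m$occ_freq_num, exp_tab$occ_freq_num)
    expect_identical(m$occ_freq_den, exp_tab$occ_freq_den)
    expect_identical(m$rti_num, exp_tab$rti_num)
    expect_identical(m$rti_den, exp_tab$rti_den)
  }
})

test_that("single-site accessors agree with the vectorized driver", {
  recs <- hand_fixture()
  expect_equal(return_date(recs, "B", "2019/20"), 52L)
  expect_true(is.na(return_date(recs, "C", "2019/20")))
  expect_equal(return_date(recs, "E", "2019/20", "pair"), 54L)
  f <- occupancy_frequency(recs, "B", "2019/20")
  expect_equal(c(f$num, f$den), c(5L, 7L))
  r <- relative_time_investment(recs, "D", "2019/20")
  expect_equal(r$value, 3 / 4)
  expect_error(occupancy_frequency(recs, "C", "2019/20"), "never occupied")
  expect_error(return_date(recs, "ZZ", "2019/20"), "unknown site")
})

test_that("survey ledger counts scorable images and honors gaps", {
  recs <- hand_fixture()
  led <- build_survey_ledger(recs)
  expect_equal(nrow(led$days), 9)          # day 53 missing
  expect_true(all(led$days$n_images == 2))
  expect_false(53 %in% led$days$season_day)
  dup <- rbind(recs, recs[1, ])
  expect_error(build_survey_ledger(dup), "duplicate")
  # declared gap with records inside is flagged
  gs <- data.frame(season = "2019/20", subcolony = 1, start_day = 50,
                   end_day = 50)
  expect_error(build_survey_ledger(recs, gs), "inside declared gap")
})

test_that("ledger day counts match the generator's survey log", {
  col <- small_colony()
  led <- build_survey_ledger(col$image_scores)
  agg <- aggregate(season_day ~ subcolony + season, data = led$days,
                   FUN = length)
  log <- col$survey_log[order(col$survey_log$subcolony, col$survey_log$season), ]
  agg <- agg[order(agg$subcolony, agg$season), ]
  expect_equal(agg$season_day, log$n_days)
})

test_that("metric invariants hold on simulated data", {
  col <- small_colony()
  m_any <- compute_metrics(col$image_scores)
  m_pair <- compute_metrics(col$image_scores, presence_filter = "pair")
  ok <- !is.na(m_any$occ_freq)
  expect_true(all(m_any$occ_freq[ok] >= 0 & m_any$occ_freq[ok] <= 1))
  expect_true(all(m_any$occ_freq_num <= m_any$occ_freq_den))
  expect_true(all(m_any$rti_num <= m_any$rti_den))
  # any-filter numerators dominate pair-filter numerators
  j <- match(paste(m_pair$site_id, m_pair$season),
             paste(m_any$site_id, m_any$season))
  expect_true(all(m_pair$occ_freq_num <= m_any$occ_freq_num[j]))
  expect_true(all(m_pair$rti_num <= m_any$rti_num[j]))
  expect_error(compute_metrics(transform(col$image_scores,
                                         count = replace(count, 1, 3L))),
               "count outside")
})

test_that("standardization centers and scales within groups and is idempotent", {
  s <- standardize(c(2, 4), c("g", "g"))
  expect_equal(s$z, c(-1, 1) / sqrt(2))
  v <- rnorm(40)
  g <- rep(c("a", "b"), each = 20)
  z1 <- standardize(v, g)$z
  for (gg in c("a", "b")) {
    expect_equal(mean(z1[g == gg]), 0)
    expect_equal(sd(z1[g == gg]), 1)
  }
  expect_equal(standardize(z1, g)$z, z1, tolerance = 1e-12)
  expect_error(standardize(c(1, 1, 2), c("a", "a", "b")), "degenerate group 'a'")
  # natural-unit back-transformation: a z-scale slope of -4.67 days/SD with
  # a quality SD near 0.28 means ~1 day earlier per 6% increase in quality
  q <- c(0.2, 0.48, 0.76, 0.9, 0.35, 0.62)
  s2 <- standardize(q, rep("g", 6))
  days_per_6pct <- -4.67 * 0.06 / s2$group_sd[1]
  expect_equal(days_per_6pct, -4.67 * 0.06 / sd(q))
  expect_lt(abs(days_per_6pct + 1), 0.35)
})

test_that("colony summaries behave on degenerate colonies", {
  recs <- hand_fixture()
  cs <- colony_summaries(recs[recs$site_id == "A", ])
  expect_true(all(cs$daily$prop_occupied == 1))
  cs2 <- colony_summaries(recs[recs$site_id == "E", ])
  expect_true(all(cs2$daily$prop_occupied %in% c(0, 1)))
  cs3 <- colony_summaries(recs)
  expect_true(all(cs3$daily$prop_occupied >= 0 & cs3$daily$prop_occupied <= 1))
  expect_true("all" %in% cs3$hourly$month)
})
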