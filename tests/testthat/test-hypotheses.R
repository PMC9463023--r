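test_that("hypothesis model sets run end to end on synthetic data", {
  col <- small_colony()
  m <- compute_metrics(col$image_scores)
  md <- prepare_model_data(m, col$breeding, col$sites)
  expect_true(all(c("quality_z", "return_z", "freq_z", "rti_z",
                    "laydate_z", "subcolony_season") %in% names(md)))
  # within-group standardization held by construction
  for (v in c("quality_z", "return_z")) {
    mns <- tapply(md[[v]], md$subcolony_season, mean)
    expect_true(all(abs(mns) < 1e-10))
  }

  a1 <- suppressWarnings(fit_hypothesis(md, "assoc1"))
  expect_s3_class(a1$chosen, "cw_fit")
  expect_true(a1$rule %in% c("delta>2", "parsimony"))

  a2 <- suppressWarnings(fit_hypothesis(md, "assoc2"))
  expect_true(any(grepl("return_z:freq_z",
                        vapply(a2$fits, function(f) f$label, ""))))

  h1 <- suppressWarnings(fit_hypothesis(md, "1"))
  expect_named(h1, c("return_day", "occ_freq", "rti"))
  # quality effects carry through: positive on frequency, negative on return
  co <- h1$occ_freq$chosen$coefficients
  if ("quality_z" %in% co$term)
    expect_gt(co$estimate[co$term == "quality_z"], 0)

  h2b <- suppressWarnings(fit_hypothesis(md, "2b"))
  expect_s3_class(h2b$chosen, "cw_fit")
  expect_equal(h2b$chosen$spec$family, "binomial")
})
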