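# Longitudinal response metrics and ADC-based lesion classification.

small_cohort <- function(seed = 2) {
  simulate_cohort(n_per_group = 3, n_lesions_mean = 20, n_lesions_sd = 3,
                  seed = seed)
}

test_that("percent change from baseline is exact arithmetic at both levels", {
  rec <- data.frame(
    animal_id = "a1", lesion_id = rep(1:2, each = 4), group = "treated",
    week = rep(0:3, 2),
    volume_mm3 = c(1, 1.2, 1.3, 1.39, 2, 2, 2, 2)
  )
  pc <- percent_change_from_baseline(rec, level = "lesion")
  expect_equal(pc$pct_change[pc$lesion_id == 1 & pc$week == 3], 39)
  expect_equal(pc$pct_change[pc$lesion_id == 2], rep(0, 4))
  tot <- percent_change_from_baseline(rec, level = "animal_total")
  expect_equal(tot$pct_change[tot$week == 3], 100 * (3.39 - 3) / 3)
  # scale invariance: units of volume cancel
  rec2 <- rec; rec2$volume_mm3 <- rec2$volume_mm3 * 1000
  pc2 <- percent_change_from_baseline(rec2, level = "lesion")
  expect_equal(pc2$pct_change, pc$pct_change)
  # zero baseline: series dropped and counted
  rec3 <- rec; rec3$volume_mm3[rec3$lesion_id == 2 & rec3$week == 0] <- 0
  pc3 <- percent_change_from_baseline(rec3, level = "lesion")
  expect_false(any(pc3$lesion_id == 2))
  expect_equal(attr(pc3, "n_skipped"), 1L)
})

test_that("per-lesion trends are OLS slopes per day with honest group summaries", {
  rec <- data.frame(
    animal_id = "a1", lesion_id = rep(1:3, times = c(4, 2, 1)),
    group = "control",
    week = c(0:3, 0, 3, 0),
    volume_mm3 = c(2 + 0.1 * (0:3) * 7, 1.0, 0.37, 5)
  )
  tr <- lesion_trend(rec, "volume_mm3")
  expect_equal(tr$slopes$slope_per_day[tr$slopes$lesion_id == 1], 0.1,
               tolerance = 1e-12)
  expect_equal(tr$slopes$slope_per_day[tr$slopes$lesion_id == 2],
               (0.37 - 1) / 21, tolerance = 1e-12) # -0.03/day
  expect_equal(tr$n_skipped, 1L) # single-timepoint lesion skipped, counted
  expect_equal(tr$summary$n, 2L)
})

test_that("ADC classification applies thresholds with the documented tie rule", {
  expect_equal(classify_lesion(0.0030), "cystic")
  expect_equal(classify_lesion(0.0010), "papillary")
  expect_equal(classify_lesion(0.0016), "solid_other")
  # boundaries go to the lower class
  expect_equal(classify_lesion(0.0022), "solid_other")
  expect_equal(classify_lesion(0.0012), "papillary")
  expect_error(classify_lesion(0.002, cystic_threshold = 0.001,
                               papillary_threshold = 0.002), "configuration")
  # monotone in ADC
  adc <- sort(runif(100, 5e-4, 4e-3))
  cls <- classify_lesion(adc)
  ord <- c(papillary = 1, solid_other = 2, cystic = 3)
  expect_true(all(diff(ord[cls]) >= 0))
})

test_that("the cohort generator reproduces its configured group effects", {
  co <- small_cohort(seed = 5)
  expect_true(all(table(paste(co$animal_id, co$lesion_id, co$week)) == 1))
  pc <- percent_change_from_baseline(co, level = "lesion")
  w3 <- aggregate(pct_change ~ group, data = pc[pc$week == 3, ], FUN = mean)
  expect_lt(abs(w3$pct_change[w3$group == "control"] - 71), 15)
  expect_lt(abs(w3$pct_change[w3$group == "treated"] - 39), 8)
  tr <- lesion_trend(co, "t2norm")
  s <- tr$summary
  expect_lt(abs(s$mean_slope_per_day[s$group == "control"] + 0.1058), 0.02)
  expect_lt(abs(s$mean_slope_per_day[s$group == "treated"] - 0.0841), 0.02)
  t1tr <- lesion_trend(co, "t1_s")$summary
  expect_gt(t1tr$mean_slope_per_day[t1tr$group == "control"], 0)
  expect_lt(t1tr$mean_slope_per_day[t1tr$group == "treated"], 0)
})
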