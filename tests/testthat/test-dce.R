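# DCE analysis: arrival detection, SPGR conversion, semi-quantitative
# parameters, Tofts forward model and fit.

test_that("bolus arrival detection handles flat, step and noisy curves", {
  expect_true(detect_bolus_arrival(rep(2, 20))$no_arrival)
  # step from 0 to 10 after 8 baseline frames: 0-based arrival index 8
  x <- c(rep(0, 8), rep(10, 12))
  a <- detect_bolus_arrival(x)
  expect_equal(a$arrival_index - 1L, 8L)
  # simulated enhancement at SNR 20, true arrival at frame 6 (1-based)
  d0 <- simulate_dce(tiny_maps(ktrans = 0.33))
  s0 <- d0$signal[1, 1, 1, ]
  sigma <- spgr_signal(1, 2.97, 40, 0.039) / 20
  set.seed(13)
  hits <- 0L
  for (r in 1:1000) {
    s <- sqrt((s0 + rnorm(50) * sigma)^2 + (rnorm(50) * sigma)^2)
    a <- detect_bolus_arrival(s)
    if (!a$no_arrival && abs(a$arrival_index - 6L) <= 1) hits <- hits + 1L
  }
  expect_gte(hits / 1000, 0.95)
})

test_that("signal-to-concentration inverts the dynamic SPGR model", {
  d <- simulate_dce(tiny_maps(ktrans = 0.33, ve = 0.3), keep_conc = TRUE)
  cur <- signal_to_concentration(d$signal[1, 1, 1, ], d$times_s,
                                 arrival_index = 6L, t1_0_s = 2.97)
  truth <- d$conc[1, 1, 1, ]
  big <- truth > 1e-6
  expect_lt(max(abs(cur$conc_mM - truth)[big] / truth[big]), 1e-8)
  expect_lt(max(abs(cur$conc_mM - truth)[!big]), 1e-10)
  # flat series converts to (numerically) zero concentration
  flat <- signal_to_concentration(rep(0.5, 50), d$times_s, 6L, 2.97)
  expect_lt(max(abs(flat$conc_mM)), 1e-12)
  # doubling the dose doubles the recovered peak (linearity)
  d2 <- simulate_dce(tiny_maps(ktrans = 0.33, ve = 0.3),
                     aif = aif_model(dose_mmol_kg = 0.54))
  c1 <- signal_to_concentration(d$signal[1, 1, 1, ], d$times_s, 6L, 2.97)
  c2 <- signal_to_concentration(d2$signal[1, 1, 1, ], d2$times_s, 6L, 2.97)
  expect_equal(max(c2$conc_mM) / max(c1$conc_mM), 2, tolerance = 1e-6)
  # unphysical frames are clipped and flagged
  s_bad <- rep(0.5, 50); s_bad[20] <- 1e4
  cb <- signal_to_concentration(s_bad, d$times_s, 6L, 2.97)
  expect_true(cb$flags[20])
  expect_true(attr(cb, "low_confidence"))
})

test_that("semi-quantitative parameters match the piecewise-linear oracle", {
  sq <- compute_semiquant(piecewise_curve())
  expect_equal(sq$peak_mM, 1.0)
  expect_equal(sq$time_to_peak_s, 50)
  expect_equal(sq$wash_in_slope, 0.02)
  expect_equal(sq$wash_out_slope, -1 / 360, tolerance = 1e-12)
  # literal sum over t in [15, 105]: 0 + 0.1 + ... + 1.0 plus 8 falling samples
  expect_equal(sq$iauc90, sum(seq(0, 1, 0.1)) + sum(1 - (1:8) * 5 / 360))
  expect_equal(sq$auc, sum(piecewise_curve()$conc_mM))
  # the time-scaled variant returns trapezoidal mM*s integrals
  sq_t <- compute_semiquant(piecewise_curve(), time_scaled = TRUE)
  expect_gt(sq_t$auc, sq$auc) # 5 s spacing scales sums up
})

test_that("semi-quantitative edge cases return explicit no-values", {
  tt <- (0:19) * 5
  # constant after arrival: peak ties broken to the arrival frame
  cc <- c(rep(0, 4), rep(0.8, 16))
  sq <- compute_semiquant(concentration_curve(tt, cc, 5L))
  expect_s3_class(sq$wash_in_slope, "mpmri_no_value")
  expect_equal(sq$wash_out_slope, 0)
  # monotone rise to the last frame: wash-out undefined
  cc2 <- c(rep(0, 4), seq(0, 1, length.out = 16))
  sq2 <- compute_semiquant(concentration_curve(tt, cc2, 5L))
  expect_s3_class(sq2$wash_out_slope, "mpmri_no_value")
  expect_equal(sq2$time_to_peak_s, tt[20] - tt[5])
})

test_that("semi-quantitative invariants hold on random non-negative curves", {
  set.seed(21)
  for (r in 1:50) {
    tt <- (0:49) * 5
    ai <- sample(4:10, 1)
    cc <- c(rep(0, ai - 1), abs(rnorm(50 - ai + 1, 0.5, 0.4)))
    sq <- compute_semiquant(concentration_curve(tt, cc, ai))
    expect_lte(sq$iauc90, sq$auc + 1e-12)
    expect_gte(sq$peak_mM, cc[ai])
    expect_gte(sq$time_to_peak_s, 0)
  }
})

test_that("the closed-form Tofts solution matches numerical convolution", {
  aif <- aif_model()
  tt <- seq(0, 245, by = 5)
  for (p in list(c(0.33, 0.3), c(0.04, 0.3), c(1.2, 0.8))) {
    ct <- tofts_conc(tt, 25, p[1], p[2], aif)
    cn <- tofts_conc_numeric(tt, 25, p[1], p[2], aif, grid_s = 0.1)
    expect_lt(max(abs(ct - cn) / pmax(abs(cn), 1e-12)), 1e-6)
    expect_true(all(ct >= 0))
  }
  # decays back toward zero at long times
  expect_lt(tofts_conc(36000, 25, 0.33, 0.3, aif), 1e-3)
  # sensitivity to Ktrans is positive near arrival
  expect_gt(tofts_conc(60, 25, 0.34, 0.3, aif), tofts_conc(60, 25, 0.33, 0.3, aif))
})

test_that("Tofts fitting recovers parameters and flags degenerate input", {
  tt <- (0:49) * 5
  for (kt in c(0.04, 0.33)) {
    cc <- tofts_conc(tt, 25, kt, 0.3)
    fit <- fit_tofts(concentration_curve(tt, cc, 6L))
    expect_lt(abs(fit$ktrans_per_min - kt) / kt, 0.01)
    expect_lt(abs(fit$ve - 0.3) / 0.3, 0.01)
    expect_true(fit$converged)
    expect_equal(unname(coef(fit)["kep_per_min"]), fit$ktrans_per_min / fit$ve)
    expect_equal(predict(fit) + residuals(fit), cc, tolerance = 1e-8)
  }
  flat <- fit_tofts(concentration_curve(tt, rep(0, 50), 6L))
  expect_equal(flat$ktrans_per_min, 0)
  expect_false(flat$identifiable)
  expect_true(is.na(flat$ve))
  expect_error(fit_tofts(concentration_curve((0:5) * 5, rep(1, 6), 2L)),
               "10 post-arrival")
})
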