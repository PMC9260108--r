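# Forward simulators: closed-form signal values, noise model behavior,
# determinism under a seed.

test_that("diffusion signal follows the mono-exponential model", {
  s <- simulate_dwi(tiny_maps(pd = 1, adc = 0.002))
  expect_equal(round(s$signal[1, 1, 1, ], 4), c(0.9512, 0.6977, 0.5241, 0.3620))
  # ADC = 0 is not constructible through tissue_params, but raw maps may be
  flat <- simulate_dwi(list(pd = array(1, c(1, 1, 1)),
                            adc_mm2_s = array(0, c(1, 1, 1))))
  expect_true(all(flat$signal == 1))
  expect_error(simulate_dwi(tiny_maps(), b_values = c(-5, 100)), "non-negative")
  expect_error(diffusion_series(matrix(1, 1, 2), c(100, 100)), "increasing")
})

test_that("Rician noise biases the mean magnitude upward and is seed-reproducible", {
  m <- tiny_maps(pd = 0.3, adc = 0.002, n = 1e4)
  s1 <- simulate_dwi(m, b_values = c(25, 508), noise_sigma = 0.15, seed = 11)
  s2 <- simulate_dwi(m, b_values = c(25, 508), noise_sigma = 0.15, seed = 11)
  expect_identical(s1$signal, s2$signal)
  noiseless <- 0.3 * exp(-508 * 0.002)
  expect_gt(mean(s1$signal[, 1, 1, 2]), noiseless)
})

test_that("SPGR signal matches the closed form, vanishes as T1 grows, and has one Ernst maximum", {
  expect_equal(spgr_signal(1, 1, 40, 0.039),
               sin(40 * pi / 180) * (1 - exp(-0.039)) /
                 (1 - exp(-0.039) * cos(40 * pi / 180)))
  expect_lt(spgr_signal(1, 1e9, 40, 0.039), 1e-9)
  ang <- c(2, 5, 10, 15, 20, 30, 40)
  sig <- simulate_vfa(tiny_maps(t1_s = 2.97))$signal[1, 1, 1, ]
  d <- diff(sig)
  expect_equal(sum(diff(sign(d)) != 0), 1) # rise then fall, single interior max
  expect_error(simulate_vfa(tiny_maps(), flip_angles_deg = c(0, 10)), "flip angle")
})

test_that("DCE simulation: zero Ktrans gives a flat series; kinetics order peaks correctly", {
  flat <- simulate_dce(tiny_maps(ktrans = 0), keep_conc = TRUE)
  expect_true(all(flat$conc == 0))
  expect_equal(max(flat$signal) - min(flat$signal), 0)
  hi <- simulate_dce(tiny_maps(ktrans = 0.33), keep_conc = TRUE)
  lo <- simulate_dce(tiny_maps(ktrans = 0.04), keep_conc = TRUE)
  ct_hi <- hi$conc[1, 1, 1, ]; ct_lo <- lo$conc[1, 1, 1, ]
  expect_gt(max(ct_hi), max(ct_lo))
  expect_lt(which.max(ct_hi), which.max(ct_lo)) # earlier time-to-peak
  # inconsistent pharmacokinetic maps are rejected
  bad <- tiny_maps(ktrans = 0.3); bad$ve[] <- 0
  expect_error(simulate_dce(bad), "ve > 0")
  expect_error(simulate_dce(tiny_maps(), arrival_s = 1e5), "arrival")
})

test_that("the T2w forward model reproduces intensity ratios and saturation", {
  # two-compartment volume: lesion T2 three times the vessel T2, equal pd/T1
  m <- list(pd = array(1, c(2, 1, 1)), t1_s = array(2, c(2, 1, 1)),
            t2_ms = array(c(60, 20), c(2, 1, 1)))
  t2w <- simulate_t2w(m, te_ms = 10, tr_s = 3)
  les <- array(c(TRUE, FALSE), c(2, 1, 1)); ves <- !les
  ratio <- normalized_t2(t2w, les, ves)
  expect_lt(abs(ratio - exp(-10 / 60) / exp(-10 / 20)) / ratio, 0.01)
})
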