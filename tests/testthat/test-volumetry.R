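# Volumetry, rater emulation, agreement statistics, SNR/CNR,
# parameter correlations.

test_that("ROI volume arithmetic is exact, thickness-linear and additive", {
  g05 <- acq_geometry(c(30, 30), c(256, 256), 0.5, 8)
  g1 <- acq_geometry(c(30, 30), c(256, 256), 1, 8)
  m <- array(FALSE, c(256, 256, 8)); m[100, 100, 4] <- TRUE
  expect_equal(roi_volume(m, g05), (30 / 256)^2 * 0.5)
  expect_equal(roi_volume(m, g1), 2 * roi_volume(m, g05))
  m2 <- array(FALSE, c(256, 256, 8)); m2[10, 10, 2] <- TRUE; m2[11, 10, 2] <- TRUE
  expect_equal(roi_volume(m | m2, g1), roi_volume(m, g1) + roi_volume(m2, g1))
  expect_warning(v0 <- roi_volume(array(FALSE, c(256, 256, 8)), g1), "empty")
  expect_equal(v0, 0)
})

test_that("digitization emulates the rater: full coverage wins, thick slices overestimate", {
  g <- acq_geometry(c(30, 30), c(256, 256), 1, 14)
  vs <- voxel_size(g)
  # lesion centred on one voxel, in-plane projection confined to it
  ctr <- c((100 - 0.5) * vs[1], (120 - 0.5) * vs[2], 6.5)
  one <- lesion_spec(1, ctr, c(vs[1] / 2, vs[2] / 2, 0.45), "solid")
  roi <- digitize_lesion(one, g, fraction_threshold = 0.5)
  expect_equal(sum(roi$mask), 1L)
  expect_true(roi$mask[100, 120, 7])
  # 0.4 mm sphere mid-slab of a 1 mm slice: one slice, volume overestimated
  sph <- lesion_spec(2, c(10, 15, 6.5), rep(0.2, 3), "solid")
  roi2 <- digitize_lesion(sph, g)
  expect_equal(sum(apply(roi2$mask, 3, any)), 1L)
  expect_gte(roi_volume(roi2), sph$volume_mm3)
  # fully out of view: empty with warning
  far <- lesion_spec(3, c(90, 15, 6.5), rep(0.2, 3), "solid")
  expect_warning(roi3 <- digitize_lesion(far, g), "outside")
  expect_equal(sum(roi3$mask), 0L)
})

test_that("digitized volumes converge to the analytic volume with resolution", {
  sph <- lesion_spec(1, c(10.06, 15.03, 7.02), rep((3 / (4 * pi))^(1 / 3), 3), "solid")
  errs <- vapply(list(
    acq_geometry(c(30, 30), c(128, 128), 1, 14),
    acq_geometry(c(30, 30), c(256, 256), 0.5, 28),
    acq_geometry(c(30, 30), c(512, 512), 0.25, 56)
  ), function(g) {
    abs(roi_volume(digitize_lesion(sph, g)) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # the projection rater model converges first-order in slice thickness,
  # so the residual at 0.25 mm slices is still a few tenths
  expect_lt(errs[3], 0.3)
})

test_that("Bland-Altman matches hand computation and handles degenerate input", {
  ba <- bland_altman(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(4 / 3), tolerance = 1e-4) # 1.1547
  expect_equal(ba$loa_high, 1.96 * sqrt(4 / 3), tolerance = 1e-4) # 2.2632
  a <- c(1, 2, 3, 4)
  ba2 <- bland_altman(a, 2 * a)
  expect_equal(ba2$pearson_r, 1)
  expect_equal(ba2$bias, -mean(a))
  same <- bland_altman(rep(2, 5), rep(2, 5))
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))
  expect_s3_class(same$pearson_r, "mpmri_no_value")
  expect_error(bland_altman(1, 1), "2 complete pairs")
})

test_that("agreement statistics equal a first-principles recomputation", {
  set.seed(31)
  for (r in 1:100) {
    n <- sample(5:40, 1)
    a <- rnorm(n, 1, 0.5)
    b <- a + rnorm(n, 0.1, 0.3)
    ba <- bland_altman(a, b)
    br <- bland_altman_brute(a, b)
    expect_equal(ba$bias, br$bias, tolerance = 1e-12)
    expect_equal(ba$loa_low, br$loa_low, tolerance = 1e-12)
    expect_equal(ba$loa_high, br$loa_high, tolerance = 1e-12)
    expect_equal(ba$pearson_r, br$r, tolerance = 1e-12)
    expect_equal(ba$pearson_p, br$p, tolerance = 1e-9)
    expect_lte(ba$loa_low, ba$bias)
    expect_gte(ba$loa_high, ba$bias)
  }
})

test_that("SNR and CNR follow their definitions and reject flat noise", {
  img <- array(0, c(30, 1, 1))
  img[1:10] <- 100; img[11:20] <- 60
  set.seed(8); img[21:30] <- rnorm(10, 0, 5)
  sroi <- array(c(rep(TRUE, 10), rep(FALSE, 20)), c(30, 1, 1))
  rroi <- array(c(rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 10)), c(30, 1, 1))
  nroi <- array(c(rep(FALSE, 20), rep(TRUE, 10)), c(30, 1, 1))
  got <- snr_cnr(img, sroi, rroi, nroi)
  ns <- sd(img[21:30])
  expect_equal(got$snr, 100 / ns)
  expect_equal(got$cnr, 40 / ns)
  expect_error(snr_cnr(array(1, c(4, 1, 1)), array(TRUE, c(4, 1, 1)),
                       noise_roi = array(TRUE, c(4, 1, 1))), "zero standard deviation")
})

test_that("2D vs 3D SNR ratio tracks the forward-model signal ratio", {
  # same tissue, equal noise; TR 3 s (2D FSE) vs 200 ms (3D FSE)
  n <- 4000
  m <- tiny_maps(pd = 1, t1_s = 1.7, t2_ms = 32, n = n)
  sigma <- 0.01
  s2d <- simulate_t2w(m, te_ms = 10, tr_s = 3, noise_sigma = sigma, seed = 41)
  s3d <- simulate_t2w(m, te_ms = 9, tr_s = 0.2, noise_sigma = sigma, seed = 42)
  # append a pure-noise background region at the same sigma to each image
  set.seed(43)
  bg <- rnorm(n, 0, sigma)
  img2 <- array(c(s2d$signal, bg), c(2 * n, 1, 1))
  img3 <- array(c(s3d$signal, bg), c(2 * n, 1, 1))
  sroi <- array(c(rep(TRUE, n), rep(FALSE, n)), c(2 * n, 1, 1))
  nroi <- !sroi
  snr2 <- snr_cnr(img2, sroi, noise_roi = nroi)$snr
  snr3 <- snr_cnr(img3, sroi, noise_roi = nroi)$snr
  want <- ((1 - exp(-3 / 1.7)) * exp(-10 / 32)) /
    ((1 - exp(-0.2 / 1.7)) * exp(-9 / 32))
  expect_lt(abs(snr2 / snr3 - want) / want, 0.05)
})

test_that("parameter correlations drop missing rows and flag tiny samples", {
  t1 <- data.frame(x = c(-1, 0, 1), y = c(1, -2, 1))
  got <- correlate_parameters(t1, "x", "y")
  expect_equal(got$r, 0, tolerance = 1e-12)
  t2 <- data.frame(x = 1:10, y = 1:10)
  got2 <- correlate_parameters(t2, "x", "y")
  expect_equal(got2$r, 1)
  expect_lt(got2$p, 1e-8)
  t3 <- data.frame(x = c(1, 2, NA, 4), y = c(2, NA, 3, 8))
  expect_s3_class(correlate_parameters(t3, "x", "y"), "mpmri_no_value")
  # direction check on a synthetic lesion table: Ktrans decreasing in volume
  set.seed(17)
  vol <- exp(runif(40, log(0.016), log(5.12)))
  tab <- data.frame(volume_mm3 = vol,
                    ktrans = 0.4 - 0.05 * log(vol) + rnorm(40, 0, 0.03))
  expect_lt(correlate_parameters(tab, "volume_mm3", "ktrans")$r, 0)
})

test_that("lesion labels match across slice thicknesses by maximal overlap", {
  ga <- acq_geometry(c(30, 30), c(64, 64), 1, 14)
  gb <- acq_geometry(c(30, 30), c(64, 64), 0.5, 28)
  l1 <- lesion_spec(1, c(10, 15, 7), rep(0.8, 3), "cystic")
  l2 <- lesion_spec(2, c(20, 15, 7), rep(0.8, 3), "solid")
  lab <- function(g) {
    arr <- array(0L, geometry_dim(g))
    for (l in list(l1, l2)) {
      roi <- digitize_lesion(l, g)
      arr[roi$mask] <- l$lesion_id
    }
    arr
  }
  m <- match_lesion_labels(lab(ga), lab(gb), ga, gb)
  expect_equal(m$lesion_b[m$lesion_a == 1], 1L)
  expect_equal(m$lesion_b[m$lesion_a == 2], 2L)
})
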