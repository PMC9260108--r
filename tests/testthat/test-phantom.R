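# Phantom generation: geometry arithmetic, lesion rasterization,
# population statistics, determinism.

test_that("geometry owns voxel-size arithmetic and rejects bad inputs", {
  g <- acq_geometry(c(30, 30), c(256, 256), slice_thickness_mm = 0.5, n_slices = 28)
  expect_equal(voxel_size(g), c(30 / 256, 30 / 256, 0.5))
  expect_equal(voxel_volume(g), (30 / 256)^2 * 0.5)
  expect_equal(geometry_dim(g), c(256L, 256L, 28L))
  expect_error(acq_geometry(c(-30, 30), c(256, 256)))
  expect_error(acq_geometry(c(30, 30), c(256, 256), slice_thickness_mm = 0))
})

test_that("an empty lesion list leaves the background composition untouched", {
  spec <- phantom_spec(lesions = list())
  g <- acq_geometry(c(30, 30), c(32, 32), 1, 14)
  ph <- make_phantom(spec, g)
  expect_true(all(ph$lesion_fraction == 0))
  expect_true(all(ph$label == 0))
  tis <- spec$tissues
  want <- array(tis$background$adc_mm2_s, geometry_dim(g))
  want[ph$kidney_mask] <- tis$parenchyma$adc_mm2_s
  want[ph$vessel_mask] <- tis$vessel$adc_mm2_s
  expect_equal(ph$maps$adc_mm2_s, want)
})

test_that("supersampled volume fractions reproduce the analytic ellipsoid volume", {
  g <- acq_geometry(c(30, 30), c(256, 256), 0.5, 28)
  l <- lesion_spec(1, c(10, 15, 7), rep(0.62, 3), "cystic")
  fr <- lesion_fractions(l, g, supersample = 4, mode = "volume")
  vol <- sum(fr$fraction) * voxel_volume(g)
  expect_equal(l$volume_mm3, 4 / 3 * pi * 0.62^3)
  expect_lt(abs(vol - l$volume_mm3) / l$volume_mm3, 0.02)
  # holds down to the smallest lesion of the study at this resolution
  tiny <- lesion_spec(2, c(10.03, 15.04, 7.07), rep((3 * 0.016 / (4 * pi))^(1 / 3), 3), "solid")
  fr2 <- lesion_fractions(tiny, g, supersample = 8, mode = "volume")
  vol2 <- sum(fr2$fraction) * voxel_volume(g)
  expect_lt(abs(vol2 - 0.016) / 0.016, 0.02)
})

test_that("drawn lesion populations follow the configured count and size range", {
  spec <- phantom_spec(seed = 7)
  lesions <- draw_lesions(spec)
  vols <- vapply(lesions, function(l) l$volume_mm3, numeric(1))
  expect_true(all(vols >= 0.016 - 1e-9) && all(vols <= 5.12 + 1e-9))
  # count is one truncated-normal draw; across seeds it must center near 36
  counts <- vapply(1:40, function(s) length(draw_lesions(spec, seed = s)), numeric(1))
  expect_gt(mean(counts), 36 - 3)
  expect_lt(mean(counts), 36 + 3)
  expect_gt(sd(counts), 2)
  # reproducibility under a fixed seed
  expect_identical(draw_lesions(spec), draw_lesions(spec))
})

test_that("phantom rasterization is deterministic, conserves tissue fractions and honors lesion priority", {
  spec <- phantom_spec(seed = 3)
  g <- acq_geometry(c(30, 30), c(48, 48), 1, 14)
  ph1 <- make_phantom(spec, g)
  ph2 <- make_phantom(spec, g)
  expect_identical(ph1$maps, ph2$maps)
  expect_true(all(ph1$lesion_fraction >= 0 & ph1$lesion_fraction <= 1 + 1e-12))
  # overlapping lesions: deterministic priority by lesion_id
  # voxel-centre-aligned so interior voxels are fully inside lesion 1
  l1 <- lesion_spec(1, c(10.3125, 15.3125, 6.5), rep(1.2, 3), "cystic")
  l2 <- lesion_spec(2, c(10.3125, 15.3125, 6.5), rep(1.2, 3), "solid")
  pho <- make_phantom(phantom_spec(lesions = list(l1, l2)), g)
  core <- pho$lesion_fraction > 0.99
  expect_true(all(pho$label[core] == 1L))
  # voxels fully inside lesion 1 carry its parameters; lesion 2 gets no room
  fr1 <- lesion_fractions(l1, g, mode = "volume")
  interior <- array(FALSE, geometry_dim(g))
  interior[fr1$lo[1]:fr1$hi[1], fr1$lo[2]:fr1$hi[2], fr1$lo[3]:fr1$hi[3]] <-
    fr1$fraction >= 1
  expect_true(any(interior))
  expect_true(all(abs(pho$maps$adc_mm2_s[interior] - l1$params$adc_mm2_s) < 1e-9))
  expect_true(all(pho$lesion_fraction <= 1 + 1e-12))
})

test_that("lesions beyond the field of view are clipped or dropped with a warning", {
  g <- acq_geometry(c(30, 30), c(32, 32), 1, 8)
  edge <- lesion_spec(1, c(29.8, 15, 4), rep(1, 3), "solid")
  expect_warning(make_phantom(phantom_spec(lesions = list(edge)), g), "clipped")
  gone <- lesion_spec(1, c(50, 15, 4), rep(1, 3), "solid")
  expect_warning(make_phantom(phantom_spec(lesions = list(gone)), g), "outside")
})
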