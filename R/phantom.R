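#' Phantom specification
#'
#' Ground-truth description of one virtual animal: two ellipsoidal kidneys,
#' a vessel reference, a lesion population and the tissue library. Lesions
#' can be given explicitly or drawn from the study's statistical structure:
#' a per-animal count from Normal(36, 5.7) truncated at >= 1 and lesion
#' volumes log-uniform over 0.016-5.12 mm^3. With a fixed seed, generation is
#' reproducible.
#'
#' Kidney and vessel shapes are ellipsoids `(center_mm, radii_mm)` in world
#' coordinates; the defaults fit a 30 x 30 mm field of view with a 14 mm
#' slab.
#'
#' @param kidneys list of two ellipsoids, each `list(center_mm, radii_mm)`.
#' @param vessel a reference-vessel ellipsoid, same form (used for
#'   blood-normalized T2 intensity).
#' @param lesions optional list of [lesion_spec()]; if `NULL`, lesions are
#'   drawn by [draw_lesions()] when the phantom is built.
#' @param n_lesions_mean,n_lesions_sd lesion-count distribution per animal.
#' @param volume_range_mm3 log-uniform lesion-volume range (mm^3).
#' @param class_probs named probabilities for cystic/papillary/solid.
#' @param tissues tissue library, see [tissue_library()].
#' @param seed integer seed driving lesion generation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kidneys = default_kidneys(), vessel = default_vessel(),
                         lesions = NULL,
                         n_lesions_mean = 36, n_lesions_sd = 5.7,
                         volume_range_mm3 = c(0.016, 5.12),
                         class_probs = c(cystic = 0.61, papillary = 0.18, solid = 0.21),
                         tissues = tissue_library(), seed = 1L) {
  stopifnot(
    length(kidneys) == 2,
    all(vapply(kidneys, function(k) length(k$center_mm) == 3 && length(k$radii_mm) == 3, TRUE)),
    length(volume_range_mm3) == 2, volume_range_mm3[1] > 0,
    volume_range_mm3[2] > volume_range_mm3[1],
    n_lesions_mean > 0, n_lesions_sd >= 0,
    all(names(class_probs) %in% c("cystic", "papillary", "solid")),
    abs(sum(class_probs) - 1) < 1e-8
  )
  s <- list(
    kidneys = kidneys, vessel = vessel, lesions = lesions,
    n_lesions_mean = n_lesions_mean, n_lesions_sd = n_lesions_sd,
    volume_range_mm3 = as.numeric(volume_range_mm3),
    class_probs = class_probs, tissues = tissues, seed = as.integer(seed)
  )
  class(s) <- "phantom_spec"
  s
}

#' Default bilateral kidney geometry
#' @param fov_mm in-plane field of view (mm).
#' @param slab_mm through-plane slab the kidneys should fit (mm).
#' @return List of two ellipsoids.
#' @export
default_kidneys <- function(fov_mm = c(30, 30), slab_mm = 14) {
  zc <- slab_mm / 2
  zr <- min(5, 0.36 * slab_mm)
  list(
    list(center_mm = c(fov_mm[1] * 0.32, fov_mm[2] / 2, zc), radii_mm = c(3.5, 4.5, zr)),
    list(center_mm = c(fov_mm[1] * 0.68, fov_mm[2] / 2, zc), radii_mm = c(3.5, 4.5, zr))
  )
}

#' Default reference vessel (aorta-like, midline)
#' @param fov_mm in-plane field of view (mm).
#' @param slab_mm through-plane slab (mm).
#' @export
default_vessel <- function(fov_mm = c(30, 30), slab_mm = 14) {
  list(center_mm = c(fov_mm[1] / 2, fov_mm[2] / 2, slab_mm / 2),
       radii_mm = c(0.5, 0.5, 0.42 * slab_mm))
}

#' Draw a lesion population
#'
#' Samples the per-animal lesion count from Normal(`n_lesions_mean`,
#' `n_lesions_sd`) rounded and truncated at 1, lesion volumes log-uniformly
#' over `volume_range_mm3`, mild random axis anisotropy at fixed volume,
#' tissue classes from `class_probs`, and centres uniformly inside the
#' kidneys (kept away from the kidney surface so lesions stay in-slab).
#'
#' @param spec a [phantom_spec()].
#' @param seed overrides `spec$seed` when not `NULL`.
#' @return List of [lesion_spec()], ids 1..n.
#' @export
draw_lesions <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(seed)) seed <- spec$seed
  with_seed(seed, {
    n <- max(1L, as.integer(round(stats::rnorm(1, spec$n_lesions_mean, spec$n_lesions_sd))))
    vol <- exp(stats::runif(n, log(spec$volume_range_mm3[1]), log(spec$volume_range_mm3[2])))
    r_eq <- (3 * vol / (4 * pi))^(1 / 3)
    f1 <- stats::runif(n, 0.85, 1.18)
    f2 <- stats::runif(n, 0.85, 1.18)
    classes <- sample(names(spec$class_probs), n, replace = TRUE, prob = spec$class_probs)
    which_kid <- sample(c(1L, 2L), n, replace = TRUE)
    u <- runif_ball(n)
    lapply(seq_len(n), function(i) {
      radii <- r_eq[i] * c(f1[i], f2[i], 1 / (f1[i] * f2[i]))
      kid <- spec$kidneys[[which_kid[i]]]
      room <- pmax(kid$radii_mm * 0.9 - radii, 0)
      center <- kid$center_mm + u[i, ] * room
      lesion_spec(i, center, radii, classes[i],
                  params = spec$tissues[[classes[i]]])
    })
  })
}

# Ellipsoid membership of voxel centres -> logical array on the full grid.
ellipsoid_mask <- function(ellipsoid, geometry) {
  x <- axis_centers(geometry, 1)
  y <- axis_centers(geometry, 2)
  z <- axis_centers(geometry, 3)
  ux <- ((x - ellipsoid$center_mm[1]) / ellipsoid$radii_mm[1])^2
  uy <- ((y - ellipsoid$center_mm[2]) / ellipsoid$radii_mm[2])^2
  uz <- ((z - ellipsoid$center_mm[3]) / ellipsoid$radii_mm[3])^2
  outer(outer(ux, uy, "+"), uz, "+") <= 1
}

# Bounding box (1-based voxel index ranges) of a lesion on a grid, padded by
# one voxel and clipped to the grid. Also reports whether clipping occurred
# and whether the lesion misses the grid entirely.
lesion_bbox <- function(lesion, geometry, pad = 1L) {
  vs <- voxel_size(geometry)
  d <- geometry_dim(geometry)
  lo <- floor((lesion$center_mm - lesion$radii_mm) / vs) + 1L - pad
  hi <- ceiling((lesion$center_mm + lesion$radii_mm) / vs) + pad
  outside <- any(hi < 1L) || any(lo > d)
  clipped <- any(lo < 1L) || any(hi > d)
  list(lo = pmax(lo, 1L), hi = pmin(hi, d), outside = outside, clipped = clipped)
}

#' Supersampled lesion fractions on a voxel grid
#'
#' Computes, for every voxel in the lesion's bounding box, either the 3D
#' volume fraction occupied by the lesion (`mode = "volume"`, used for
#' partial-volume signal mixing) or the in-plane fraction of the pixel
#' covered by the lesion's projection through the slice slab
#' (`mode = "projected"`, used by the rater-emulating [digitize_lesion()]).
#' Fractions are estimated by `supersample` subsamples per axis (default 4,
#' i.e. 64 subsamples per voxel) and are deterministic.
#'
#' @param lesion a [lesion_spec()].
#' @param geometry an [acq_geometry()].
#' @param supersample subsamples per axis (>= 2).
#' @param mode `"volume"` or `"projected"`.
#' @return `NULL` if the lesion misses the grid; otherwise a list with the
#'   bounding box `lo`/`hi` (1-based index ranges), a `fraction` array over
#'   the box, and a `clipped` flag.
#' @export
lesion_fractions <- function(lesion, geometry, supersample = 4L,
                             mode = c("volume", "projected")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lesion, "lesion_spec"), supersample >= 2)
  s <- as.integer(supersample)
  bb <- lesion_bbox(lesion, geometry)
  if (bb$outside) return(NULL)
  vs <- voxel_size(geometry)
  nb <- bb$hi - bb$lo + 1L
  offs <- (seq_len(s) - 0.5) / s
  sub_coord <- function(axis) {
    idx0 <- (bb$lo[axis]:bb$hi[axis]) - 1L # 0-based voxel index
    as.vector(outer(offs, idx0, "+")) * vs[axis] # subsample index fastest
  }
  cx <- lesion$center_mm; rr <- lesion$radii_mm
  ux <- ((sub_coord(1) - cx[1]) / rr[1])^2
  uy <- ((sub_coord(2) - cx[2]) / rr[2])^2
  uz <- ((sub_coord(3) - cx[3]) / rr[3])^2
  inside <- outer(outer(ux, uy, "+"), uz, "+") <= 1
  dim(inside) <- c(s, nb[1], s, nb[2], s, nb[3])
  if (mode == "volume") {
    frac <- apply(inside, c(2, 4, 6), mean)
  } else {
    # any hit along z within the slab -> pixel subsample counts as covered
    proj <- apply(inside, c(1, 2, 3, 4, 6), max)
    frac <- apply(proj, c(2, 4, 5), mean)
  }
  list(lo = bb$lo, hi = bb$hi, fraction = frac, clipped = bb$clipped)
}

#' Build a digital phantom
#'
#' Rasterizes the phantom specification onto an acquisition grid. Voxels
#' covered partly by a lesion get the volume-fraction-weighted mixture of
#' the lesion's parameters and the underlying tissue; fractions come from
#' 4x-per-axis supersampling. Overlapping lesions are resolved
#' deterministically in `lesion_id` order (earlier ids claim their fraction
#' first). Lesions extending beyond the field of view are clipped with a
#' warning.
#'
#' @param spec a [phantom_spec()]; if its `lesions` is `NULL`, a population
#'   is drawn with [draw_lesions()] under `spec$seed`.
#' @param geometry an [acq_geometry()].
#' @param supersample subsamples per axis for partial-volume fractions.
#' @return An object of class `mri_phantom`: parameter maps (`pd`, `t1_s`,
#'   `t2_ms`, `adc_mm2_s`, `ktrans_per_min`, `ve`), the total lesion-fraction
#'   map, a dominant-lesion `label` map, kidney and vessel masks, the lesion
#'   list and a ground-truth `lesions` table (id, centre, radii, class,
#'   analytic volume, parameters).
#' @export
make_phantom <- function(spec, geometry, supersample = 4L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(geometry, "acq_geometry"))
  lesions <- spec$lesions
  if (is.null(lesions)) lesions <- draw_lesions(spec)
  d <- geometry_dim(geometry)

  kidney_mask <- ellipsoid_mask(spec$kidneys[[1]], geometry) |
    ellipsoid_mask(spec$kidneys[[2]], geometry)
  vessel_mask <- ellipsoid_mask(spec$vessel, geometry)

  fields <- c("pd", "t1_s", "t2_ms", "adc_mm2_s", "ktrans_per_min", "ve")
  base <- lapply(fields, function(f) {
    m <- array(spec$tissues$background[[f]], dim = d)
    m[kidney_mask] <- spec$tissues$parenchyma[[f]]
    m[vessel_mask] <- spec$tissues$vessel[[f]]
    m
  })
  names(base) <- fields
  maps <- lapply(base, identity)

  lesion_frac <- array(0, dim = d)
  label <- array(0L, dim = d)
  best_frac <- array(0, dim = d)

  for (lesion in lesions) {
    fr <- lesion_fractions(lesion, geometry, supersample, mode = "volume")
    if (is.null(fr)) {
      warning(sprintf("lesion %d lies outside the field of view and was dropped",
                      lesion$lesion_id))
      next
    }
    if (fr$clipped) {
      warning(sprintf("lesion %d extends beyond the field of view and was clipped",
                      lesion$lesion_id))
    }
    ix <- fr$lo[1]:fr$hi[1]; iy <- fr$lo[2]:fr$hi[2]; iz <- fr$lo[3]:fr$hi[3]
    room <- 1 - lesion_frac[ix, iy, iz, drop = FALSE]
    f_eff <- pmin(fr$fraction, room)
    lesion_frac[ix, iy, iz] <- lesion_frac[ix, iy, iz] + f_eff
    upd <- f_eff > best_frac[ix, iy, iz]
    lb <- label[ix, iy, iz]; lb[upd] <- lesion$lesion_id
    label[ix, iy, iz] <- lb
    bf <- best_frac[ix, iy, iz]; bf[upd] <- f_eff[upd]
    best_frac[ix, iy, iz] <- bf
    for (f in fields) {
      maps[[f]][ix, iy, iz] <- maps[[f]][ix, iy, iz] +
        f_eff * (lesion$params[[f]] - base[[f]][ix, iy, iz])
    }
  }

  gt <- do.call(rbind, lapply(lesions, function(l) {
    data.frame(
      lesion_id = l$lesion_id,
      center_x_mm = l$center_mm[1], center_y_mm = l$center_mm[2],
      center_z_mm = l$center_mm[3],
      radius_x_mm = l$radii_mm[1], radius_y_mm = l$radii_mm[2],
      radius_z_mm = l$radii_mm[3],
      tissue_class = l$tissue_class, volume_mm3 = l$volume_mm3,
      pd = l$params$pd, t1_s = l$params$t1_s, t2_ms = l$params$t2_ms,
      adc_mm2_s = l$params$adc_mm2_s,
      ktrans_per_min = l$params$ktrans_per_min, ve = l$params$ve
    )
  }))

  ph <- list(
    maps = maps, lesion_fraction = lesion_frac, label = label,
    kidney_mask = kidney_mask, vessel_mask = vessel_mask,
    lesion_list = lesions, lesions = gt, geometry = geometry, spec = spec
  )
  class(ph) <- "mri_phantom"
  ph
}

#' @export
print.mri_phantom <- function(x, ...) {
  d <- geometry_dim(x$geometry)
  cat(sprintf("MRI phantom: %d x %d x %d grid, %d lesions (%s)\n",
              d[1], d[2], d[3], nrow(x$lesions),
              paste(sprintf("%s %d", names(table(x$lesions$tissue_class)),
                            as.integer(table(x$lesions$tissue_class))),
                    collapse = ", ")))
  invisible(x)
}
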