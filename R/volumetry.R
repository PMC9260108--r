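# Lesion volumetry from stacked 2D ROIs, rater emulation, agreement
# statistics (Bland-Altman, Pearson) and SNR/CNR.

#' Lesion ROI
#'
#' A stack of per-slice binary in-plane masks for one lesion, stored as a
#' 3D logical array on its acquisition grid.
#'
#' @param mask 3D logical array matching the geometry's grid.
#' @param geometry an [acq_geometry()].
#' @param lesion_id optional integer identifier.
#' @export
lesion_roi <- function(mask, geometry, lesion_id = NA_integer_) {
  mask <- as_3d(mask)
  stopifnot(inherits(geometry, "acq_geometry"),
            all(dim(mask) == geometry_dim(geometry)))
  structure(list(mask = array(as.logical(mask), dim = dim(mask)),
                 geometry = geometry, lesion_id = as.integer(lesion_id)),
            class = "lesion_roi")
}

#' @export
print.lesion_roi <- function(x, ...) {
  cat(sprintf("lesion ROI%s: %d voxels on %d slices, volume %.4g mm3\n",
              if (is.na(x$lesion_id)) "" else paste0(" ", x$lesion_id),
              sum(x$mask), sum(apply(x$mask, 3, any)), roi_volume(x)))
  invisible(x)
}

#' ROI volume
#'
#' `volume = (voxel count) x (in-plane voxel area) x (slice thickness)`,
#' summed over slices. Linear in slice thickness and additive over
#' disjoint ROIs by construction.
#'
#' @param roi a [lesion_roi()] or 3D logical array.
#' @param geometry an [acq_geometry()]; defaults to the ROI's own.
#' @return Volume in mm^3 (0 with a warning for an empty ROI).
#' @export
roi_volume <- function(roi, geometry = NULL) {
  if (inherits(roi, "lesion_roi")) {
    if (is.null(geometry)) geometry <- roi$geometry
    roi <- roi$mask
  }
  stopifnot(inherits(geometry, "acq_geometry"))
  stopifnot(all(dim(as_3d(roi)) == geometry_dim(geometry)))
  n <- sum(roi)
  if (n == 0) warning("empty ROI: volume is zero")
  vs <- voxel_size(geometry)
  n * vs[1] * vs[2] * vs[3]
}

#' Digitize a ground-truth lesion into an ROI (rater emulation)
#'
#' Emulates the manual rater who outlines a lesion on each T2-weighted
#' slice: a pixel enters the per-slice mask when the fraction of the pixel
#' covered by the lesion's projection through that slice slab reaches
#' `fraction_threshold` (supersampled, deterministic). Because a thin
#' lesion still shows its full in-plane extent on a thick slice, this is
#' the mechanism by which thick slices overestimate small-lesion volumes;
#' the threshold is the lever controlling that overestimation.
#'
#' @param lesion a [lesion_spec()].
#' @param geometry an [acq_geometry()].
#' @param fraction_threshold in-plane coverage threshold in (0, 1],
#'   default 0.5.
#' @param supersample subsamples per axis for the coverage fractions.
#' @return A [lesion_roi()]; empty (with a warning) if the lesion lies
#'   outside the field of view.
#' @export
digitize_lesion <- function(lesion, geometry, fraction_threshold = 0.5,
                            supersample = 4L) {
  stopifnot(fraction_threshold > 0, fraction_threshold <= 1)
  d <- geometry_dim(geometry)
  mask <- array(FALSE, dim = d)
  fr <- lesion_fractions(lesion, geometry, supersample, mode = "projected")
  if (is.null(fr)) {
    warning(sprintf("lesion %d lies outside the field of view: empty ROI",
                    lesion$lesion_id))
    return(lesion_roi(mask, geometry, lesion$lesion_id))
  }
  mask[fr$lo[1]:fr$hi[1], fr$lo[2]:fr$hi[2], fr$lo[3]:fr$hi[3]] <-
    fr$fraction >= fraction_threshold
  lesion_roi(mask, geometry, lesion$lesion_id)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; bias is `mean(d)` and the limits of agreement
#' are `bias +/- 1.96 sd(d)` with the sample (n-1) standard deviation.
#' Pearson correlation of the paired values is reported alongside; when
#' either list has zero variance the correlation is an explicit no-value
#' while the bias is still returned.
#'
#' @param a,b paired measurements (equal length, >= 2 pairs).
#' @return An object of class `agreement_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `pearson_r`, `pearson_p`, `n_pairs`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- a - b
  bias <- mean(d)
  sdd <- stats::sd(d)
  if (stats::var(a) > 0 && stats::var(b) > 0) {
    ct <- stats::cor.test(a, b, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- no_value("zero variance in one of the measurement lists")
    p <- NA_real_
  }
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 pearson_r = r, pearson_p = p, n_pairs = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  rtxt <- if (is_no_value(x$pearson_r)) "undefined (zero variance)"
          else sprintf("%.3f (p = %.3g)", x$pearson_r, x$pearson_p)
  cat(sprintf(
    "Bland-Altman agreement (n = %d): bias %.4g, limits [%.4g, %.4g], Pearson r %s\n",
    x$n_pairs, x$bias, x$loa_low, x$loa_high, rtxt))
  invisible(x)
}

#' Signal-to-noise and contrast-to-noise ratio
#'
#' `SNR = mean(signal ROI) / sd(noise ROI)` and
#' `CNR = |mean(signal ROI) - mean(reference ROI)| / sd(noise ROI)`. The
#' noise ROI must sit in artifact-free background.
#'
#' @param image 3D numeric array or an object with a `signal` field.
#' @param signal_roi,reference_roi,noise_roi logical arrays (or
#'   `lesion_roi`s); `reference_roi` may be `NULL` to skip CNR.
#' @return List with `snr` and `cnr` (`cnr` `NA` without a reference).
#' @export
snr_cnr <- function(image, signal_roi, reference_roi = NULL, noise_roi) {
  vol <- if (is.list(image) && !is.null(image$signal)) image$signal else image
  get_mask <- function(r) if (inherits(r, "lesion_roi")) r$mask else as.logical(r)
  ns <- stats::sd(vol[get_mask(noise_roi)])
  if (!is.finite(ns) || ns == 0) stop("noise ROI has zero standard deviation")
  sm <- mean(vol[get_mask(signal_roi)])
  cnr <- if (is.null(reference_roi)) NA_real_ else {
    abs(sm - mean(vol[get_mask(reference_roi)])) / ns
  }
  list(snr = sm / ns, cnr = cnr)
}

#' Pearson correlation between two lesion-table parameters
#'
#' Rows with a missing value in either column are dropped (and counted);
#' the two-sided p-value uses the t distribution. Fewer than 3 complete
#' pairs yields the explicit no-value result.
#'
#' @param table data frame of per-lesion parameters.
#' @param x,y column names.
#' @param method correlation method (only `"pearson"`).
#' @return List with `r`, `p`, `n`, `n_dropped`; or a `no_value`.
#' @export
correlate_parameters <- function(table, x, y, method = "pearson") {
  stopifnot(is.data.frame(table), x %in% names(table), y %in% names(table),
            method == "pearson")
  xv <- table[[x]]; yv <- table[[y]]
  keep <- is.finite(xv) & is.finite(yv)
  n_dropped <- sum(!keep)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) {
    return(no_value(sprintf("fewer than 3 complete (%s, %s) pairs", x, y)))
  }
  ct <- stats::cor.test(xv, yv, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xv),
       n_dropped = n_dropped)
}

#' Match lesion labels between two ROI stacks by maximum overlap
#'
#' Maps each labelled lesion in `labels_a` to the label in `labels_b` with
#' which it shares the largest spatial overlap. The two stacks must share
#' the in-plane grid; slices are matched through world z-coordinates, so
#' stacks of different slice thickness over the same slab can be compared.
#'
#' @param labels_a,labels_b integer 3D label arrays (0 = background).
#' @param geometry_a,geometry_b their [acq_geometry()]s.
#' @return Data frame with `lesion_a`, `lesion_b` (`NA` when nothing
#'   overlaps) and `overlap_voxels` (counted on grid A).
#' @export
match_lesion_labels <- function(labels_a, labels_b, geometry_a, geometry_b) {
  stopifnot(all(geometry_dim(geometry_a)[1:2] == geometry_dim(geometry_b)[1:2]))
  za <- axis_centers(geometry_a, 3)
  zb <- axis_centers(geometry_b, 3)
  slice_b <- vapply(za, function(z) which.min(abs(zb - z)), integer(1))
  b_on_a <- labels_b[, , slice_b, drop = FALSE]
  ids_a <- sort(setdiff(unique(as.vector(labels_a)), 0))
  out <- lapply(ids_a, function(id) {
    hits <- b_on_a[labels_a == id]
    hits <- hits[hits != 0]
    if (length(hits) == 0) {
      data.frame(lesion_a = id, lesion_b = NA_integer_, overlap_voxels = 0L)
    } else {
      tb <- table(hits)
      data.frame(lesion_a = id,
                 lesion_b = as.integer(names(tb)[which.max(tb)]),
                 overlap_voxels = as.integer(max(tb)))
    }
  })
  do.call(rbind, out)
}
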