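# NIfTI readers/writers with YAML sidecars, and the study configuration.
# Acquisition metadata that NIfTI-1 cannot carry (frame timing, b-values,
# flip angles, dummy scans) lives in a sidecar YAML next to the image, not
# in private header extensions, for portability across tools.

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".yaml", path)
}

#' Write a volume or series as NIfTI-1 with a YAML sidecar
#'
#' Voxel dimensions are written into the NIfTI header from the geometry;
#' everything else (orientation, frame spacing, b-values, flip angles, TR,
#' dummy scans, ...) goes into `<image>.yaml`.
#'
#' @param data 3D or 4D numeric array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param geometry an [acq_geometry()].
#' @param meta named list of extra acquisition metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_image <- function(data, path, geometry, meta = list()) {
  stopifnot(inherits(geometry, "acq_geometry"),
            length(dim(data)) %in% c(3, 4))
  vs <- voxel_size(geometry)
  pix <- if (length(dim(data)) == 4) c(vs, 1) else vs
  img <- RNifti::asNifti(data)
  img <- RNifti::`pixdim<-`(img, pix)
  RNifti::writeNifti(img, path)
  side <- c(list(
    orientation = geometry$orientation,
    fov_mm = as.numeric(geometry$fov_mm),
    matrix_size = as.integer(geometry$matrix_size),
    slice_thickness_mm = geometry$slice_thickness_mm,
    n_slices = geometry$n_slices
  ), meta)
  yaml::write_yaml(side, sidecar_path(path))
  invisible(path)
}

#' Read a NIfTI-1 image and its sidecar
#'
#' Rebuilds the acquisition geometry from the header voxel dimensions and
#' cross-checks it against the sidecar: a slice-thickness or matrix
#' disagreement between the two sources is a hard error naming both, never
#' a silent preference.
#'
#' @param path NIfTI file written by [write_image()] (sidecar optional for
#'   foreign files; geometry then comes from the header alone, orientation
#'   defaults to axial).
#' @return List with `data` (array), `geometry` and `meta` (sidecar
#'   fields).
#' @export
read_image <- function(path) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  pix <- RNifti::pixdim(img)
  d <- dim(data)
  meta <- list()
  sp <- sidecar_path(path)
  orientation <- "axial"
  if (file.exists(sp)) {
    meta <- yaml::read_yaml(sp)
    if (!is.null(meta$slice_thickness_mm) &&
        abs(meta$slice_thickness_mm - pix[3]) > 1e-6) {
      stop(sprintf(
        "slice thickness mismatch: NIfTI header says %g mm, sidecar %s says %g mm",
        pix[3], sp, meta$slice_thickness_mm))
    }
    if (!is.null(meta$matrix_size) && any(meta$matrix_size != d[1:2])) {
      stop(sprintf(
        "matrix mismatch: NIfTI header says %d x %d, sidecar %s says %d x %d",
        d[1], d[2], sp, meta$matrix_size[1], meta$matrix_size[2]))
    }
    if (!is.null(meta$orientation)) orientation <- meta$orientation
  }
  geometry <- acq_geometry(
    fov_mm = pix[1:2] * d[1:2], matrix_size = d[1:2],
    slice_thickness_mm = pix[3], n_slices = d[3],
    orientation = orientation
  )
  list(data = data, geometry = geometry, meta = meta)
}

#' Read a dynamic series from NIfTI + sidecar
#'
#' The sidecar must carry `dt_s`; frame times are `t_i = i dt_s`
#' (0-based). Dummy-scan count and SPGR readout parameters are taken from
#' the sidecar when present.
#'
#' @param path 4D NIfTI written by [write_image()].
#' @return A [dynamic_series()].
#' @export
read_dynamic_series <- function(path) {
  im <- read_image(path)
  stopifnot(length(dim(im$data)) == 4)
  m <- im$meta
  if (is.null(m$dt_s)) stop("sidecar must provide dt_s for a dynamic series")
  dynamic_series(im$data, dt_s = m$dt_s,
                 n_dummy = if (is.null(m$n_dummy)) 0L else m$n_dummy,
                 arrival_s = if (is.null(m$arrival_s)) NA else m$arrival_s,
                 tr_s = if (is.null(m$tr_s)) 0.039 else m$tr_s,
                 flip_deg = if (is.null(m$flip_deg)) 40 else m$flip_deg,
                 r1_relaxivity = if (is.null(m$r1_relaxivity)) 3.4 else m$r1_relaxivity,
                 geometry = im$geometry)
}

#' Default study configuration
#'
#' The full configuration of one virtual study, mirroring the acquisition
#' protocol: T2-weighted FSE (30 x 30 mm FOV, 256 x 256, 0.5 and 1 mm
#' slices, TE 10 ms), DWI at b = 25/180/323/508 s/mm^2 (128 x 128, 1 mm),
#' VFA SPGR at 2-40 degrees with TR 39 ms, and DCE at 5 s resolution with
#' 50 frames and 40 dummy scans. Analysis defaults: r1 = 3.4 /s/mM,
#' biexponential AIF, ADC classification thresholds 0.0022/0.0012 mm^2/s,
#' rater threshold 0.5. All per-acquisition SNR values scale the Rician
#' noise as (reference tissue signal)/SNR.
#'
#' @param seed study seed; every stage derives its own substream from it.
#' @param scale optional factor in (0, 1] shrinking matrix sizes and slice
#'   counts for quick runs (lesion statistics are untouched).
#' @return Nested list of class `study_config`.
#' @export
default_study_config <- function(seed = 1L, scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  m <- function(n) max(16L, as.integer(round(n * scale)))
  cfg <- list(
    seed = as.integer(seed),
    phantom = list(n_lesions_mean = 36, n_lesions_sd = 5.7,
                   volume_range_mm3 = c(0.016, 5.12), slab_mm = 14),
    acquisitions = list(
      t2w = list(fov_mm = c(30, 30), matrix_size = rep(m(256), 2),
                 slice_thickness_mm = 0.5, te_ms = 10, tr_s = 3, snr = 40),
      dwi = list(fov_mm = c(30, 30), matrix_size = rep(m(128), 2),
                 slice_thickness_mm = 1,
                 b_values = c(25, 180, 323, 508), snr = 30),
      vfa = list(fov_mm = c(30, 30), matrix_size = rep(m(128), 2),
                 slice_thickness_mm = 1,
                 flip_angles_deg = c(2, 5, 10, 15, 20, 30, 40),
                 tr_s = 0.039, snr = 50),
      dce = list(fov_mm = c(30, 30), matrix_size = rep(m(128), 2),
                 slice_thickness_mm = 1, dt_s = 5, n_frames = 50,
                 n_dummy = 40, arrival_s = 25, tr_s = 0.039, flip_deg = 40,
                 snr = 20)
    ),
    analysis = list(
      r1_relaxivity = 3.4,
      aif = list(dose_mmol_kg = 0.27, a1_kg_l = 3.99, a2_kg_l = 4.78,
                 m1_per_min = 0.144, m2_per_min = 0.0111),
      cystic_threshold = 0.0022, papillary_threshold = 0.0012,
      fraction_threshold = 0.5
    ),
    longitudinal = list(n_per_group = 3, weeks = 0:3)
  )
  class(cfg) <- c("study_config", "list")
  cfg
}

#' Write / read a study configuration as YAML
#'
#' Round-trips losslessly; all units are explicit in the field names.
#'
#' @param config a `study_config`.
#' @param path YAML file path.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_study_config(cfg)
}

#' Validate a study configuration
#' @param config nested list.
#' @return The config, classed, or an error naming the offending field.
#' @export
validate_study_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config$seed is required")
  if (is.null(config$acquisitions)) stop("config$acquisitions is required")
  for (acq in names(config$acquisitions)) {
    blk <- config$acquisitions[[acq]]
    for (f in c("fov_mm", "matrix_size", "slice_thickness_mm")) {
      if (is.null(blk[[f]])) stop(sprintf("acquisition '%s' lacks %s", acq, f))
    }
  }
  class(config) <- c("study_config", "list")
  config
}

acq_geometry_from_block <- function(block, slab_mm) {
  acq_geometry(
    fov_mm = unlist(block$fov_mm),
    matrix_size = unlist(block$matrix_size),
    slice_thickness_mm = block$slice_thickness_mm,
    n_slices = as.integer(round(slab_mm / block$slice_thickness_mm))
  )
}
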