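# Forward simulators for the four acquisitions. All of them are
# deterministic under a fixed seed, and noiseless when noise_sigma = 0;
# noise is Rician on the magnitude signal.

#' Rician magnitude noise
#'
#' Adds Rician noise to a noiseless magnitude signal: the magnitude of the
#' signal plus complex Gaussian noise of scale `sigma` per channel. At low
#' SNR this biases the measured magnitude upward, as in magnitude MR images.
#'
#' @param s noiseless signal (any shape).
#' @param sigma Gaussian scale per quadrature channel; `<= 0` returns `s`.
#' @return Noisy magnitudes, same shape as `s`.
#' @export
rician_noise <- function(s, sigma) {
  if (sigma <= 0) return(s)
  n <- length(s)
  out <- sqrt((s + stats::rnorm(n) * sigma)^2 + (stats::rnorm(n) * sigma)^2)
  dim(out) <- dim(s)
  out
}

#' Spoiled gradient echo (SPGR) signal
#'
#' `S = pd sin(a) (1 - E1) / (1 - E1 cos(a))` with `E1 = exp(-TR/T1)`.
#' Echo-time decay is assumed folded into `pd` (constant across flip
#' angles).
#'
#' @param pd proton density / equilibrium signal.
#' @param t1_s T1 (s); vectorized.
#' @param flip_deg flip angle (degrees).
#' @param tr_s repetition time (s).
#' @export
spgr_signal <- function(pd, t1_s, flip_deg, tr_s) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_s / t1_s)
  pd * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

pull_maps <- function(maps, fields) {
  if (inherits(maps, "mri_phantom")) {
    geometry <- maps$geometry
    maps <- maps$maps
  } else {
    geometry <- attr(maps, "geometry")
  }
  stopifnot(all(fields %in% names(maps)))
  maps <- lapply(maps[fields], as_3d)
  list(maps = maps, geometry = geometry)
}

#' Construct a diffusion-weighted series
#'
#' Container for one 3D signal volume per b-value. Used both by
#' [simulate_dwi()] and to wrap measured data for [fit_adc()].
#'
#' @param signal 4D array (x, y, z, b) or a matrix (voxel, b).
#' @param b_values b-values (s/mm^2), non-negative and strictly increasing.
#' @param geometry optional [acq_geometry()].
#' @export
diffusion_series <- function(signal, b_values, geometry = NULL) {
  if (is.matrix(signal)) {
    signal <- array(signal, dim = c(nrow(signal), 1L, 1L, ncol(signal)))
  }
  stopifnot(length(dim(signal)) == 4, dim(signal)[4] == length(b_values),
            length(b_values) >= 2)
  if (any(b_values < 0)) stop("b-values must be non-negative")
  if (any(diff(b_values) <= 0)) stop("b-values must be strictly increasing")
  structure(list(signal = signal, b_values = as.numeric(b_values),
                 geometry = geometry),
            class = "diffusion_series")
}

#' Simulate a multi-b-value diffusion acquisition
#'
#' Noiseless voxel signal follows the mono-exponential model
#' `S(b) = pd exp(-b ADC)`; Rician noise of scale `noise_sigma` is applied
#' to each magnitude volume.
#'
#' @param maps an [make_phantom()] result or a named list of arrays with
#'   `pd` and `adc_mm2_s`.
#' @param b_values b-values (s/mm^2); default the study's 25, 180, 323, 508.
#' @param noise_sigma Rician scale in signal units (0 = noiseless).
#' @param seed optional RNG seed (restored afterwards).
#' @return A [diffusion_series()].
#' @export
simulate_dwi <- function(maps, b_values = c(25, 180, 323, 508),
                         noise_sigma = 0, seed = NULL) {
  pm <- pull_maps(maps, c("pd", "adc_mm2_s"))
  if (any(b_values < 0)) stop("b-values must be non-negative")
  d <- dim(pm$maps$pd)
  sig <- array(NA_real_, dim = c(d, length(b_values)))
  with_seed(seed, {
    for (i in seq_along(b_values)) {
      s <- pm$maps$pd * exp(-b_values[i] * pm$maps$adc_mm2_s)
      sig[, , , i] <- rician_noise(s, noise_sigma)
    }
  })
  diffusion_series(sig, b_values, pm$geometry)
}

#' Construct a variable-flip-angle series
#'
#' @param signal 4D array (x, y, z, angle) or matrix (voxel, angle).
#' @param flip_angles_deg flip angles in degrees, in (0, 90].
#' @param tr_s repetition time (s).
#' @param geometry optional [acq_geometry()].
#' @export
vfa_series <- function(signal, flip_angles_deg, tr_s, geometry = NULL) {
  if (is.matrix(signal)) {
    signal <- array(signal, dim = c(nrow(signal), 1L, 1L, ncol(signal)))
  }
  stopifnot(length(dim(signal)) == 4,
            dim(signal)[4] == length(flip_angles_deg), tr_s > 0)
  if (any(flip_angles_deg <= 0) || any(flip_angles_deg > 90)) {
    stop("flip angles must lie in (0, 90] degrees")
  }
  structure(list(signal = signal, flip_angles_deg = as.numeric(flip_angles_deg),
                 tr_s = as.numeric(tr_s), geometry = geometry),
            class = "vfa_series")
}

#' Simulate a variable-flip-angle SPGR acquisition
#'
#' One SPGR volume per flip angle via [spgr_signal()]; defaults follow the
#' study protocol (2, 5, 10, 15, 20, 30, 40 degrees; TR 39 ms).
#'
#' @inheritParams simulate_dwi
#' @param flip_angles_deg flip angles (degrees), each in (0, 90].
#' @param tr_s repetition time (s).
#' @return A [vfa_series()].
#' @export
simulate_vfa <- function(maps, flip_angles_deg = c(2, 5, 10, 15, 20, 30, 40),
                         tr_s = 0.039, noise_sigma = 0, seed = NULL) {
  pm <- pull_maps(maps, c("pd", "t1_s"))
  if (any(flip_angles_deg <= 0)) stop("flip angle of 0 gives no signal and cannot be fitted")
  d <- dim(pm$maps$pd)
  sig <- array(NA_real_, dim = c(d, length(flip_angles_deg)))
  with_seed(seed, {
    for (i in seq_along(flip_angles_deg)) {
      s <- spgr_signal(pm$maps$pd, pm$maps$t1_s, flip_angles_deg[i], tr_s)
      sig[, , , i] <- rician_noise(s, noise_sigma)
    }
  })
  vfa_series(sig, flip_angles_deg, tr_s, pm$geometry)
}

#' Simulate a T2-weighted fast-spin-echo image
#'
#' Signal model `S = pd (1 - exp(-TR/T1)) exp(-TE/T2)`: mono-exponential
#' T2 weighting at the effective echo time with saturation from the finite
#' repetition time. Defaults are the study's 2D FSE protocol (TE 10 ms,
#' TR 3 s).
#'
#' @inheritParams simulate_dwi
#' @param te_ms effective echo time (ms).
#' @param tr_s repetition time (s).
#' @return List of class `t2w_image` with the 3D `signal`, `te_ms`, `tr_s`
#'   and `geometry`.
#' @export
simulate_t2w <- function(maps, te_ms = 10, tr_s = 3, noise_sigma = 0, seed = NULL) {
  pm <- pull_maps(maps, c("pd", "t1_s", "t2_ms"))
  s <- pm$maps$pd * (1 - exp(-tr_s / pm$maps$t1_s)) * exp(-te_ms / pm$maps$t2_ms)
  s <- with_seed(seed, rician_noise(s, noise_sigma))
  structure(list(signal = s, te_ms = te_ms, tr_s = tr_s, geometry = pm$geometry),
            class = "t2w_image")
}

#' Construct a dynamic (DCE) series
#'
#' @param signal 4D array (x, y, z, frame) or matrix (voxel, frame).
#' @param dt_s frame spacing (s).
#' @param n_dummy number of pre-injection dummy scans (metadata only).
#' @param arrival_s bolus arrival time relative to the first retained frame
#'   (s); may be `NA` when unknown (use [detect_bolus_arrival()]).
#' @param tr_s,flip_deg SPGR readout parameters of the dynamic scan.
#' @param r1_relaxivity contrast-agent longitudinal relaxivity (1/s/mM).
#' @param aif optional [aif_model()] used to generate the series.
#' @param geometry optional [acq_geometry()].
#' @param conc optional true concentration array (kept by the simulator for
#'   round-trip testing).
#' @export
dynamic_series <- function(signal, dt_s, n_dummy = 0, arrival_s = NA,
                           tr_s = 0.039, flip_deg = 40, r1_relaxivity = 3.4,
                           aif = NULL, geometry = NULL, conc = NULL) {
  if (is.matrix(signal)) {
    signal <- array(signal, dim = c(nrow(signal), 1L, 1L, ncol(signal)))
  }
  stopifnot(length(dim(signal)) == 4, dt_s > 0, dim(signal)[4] >= 2)
  n_frames <- dim(signal)[4]
  times_s <- (seq_len(n_frames) - 1) * dt_s
  structure(list(signal = signal, times_s = times_s, dt_s = dt_s,
                 n_frames = n_frames, n_dummy = as.integer(n_dummy),
                 arrival_s = arrival_s, tr_s = tr_s, flip_deg = flip_deg,
                 r1_relaxivity = r1_relaxivity, aif = aif,
                 geometry = geometry, conc = conc),
            class = "dynamic_series")
}

#' Simulate a dynamic contrast-enhanced acquisition
#'
#' Tissue concentration follows the Tofts model driven by a biexponential
#' AIF, evaluated with the exact closed form (see [tofts_conc()]); the
#' longitudinal rate is `R1(t) = 1/T1_0 + r1 Ct(t)` and the signal is the
#' SPGR equation at each frame. Frames before bolus arrival carry baseline
#' signal only. Defaults follow the study protocol: 5 s resolution, 50
#' frames, 40 dummy scans before injection, TR 39 ms, 40 degree flip.
#'
#' @inheritParams simulate_dwi
#' @param aif an [aif_model()].
#' @param dt_s frame spacing (s).
#' @param n_frames number of retained frames (>= 2).
#' @param n_dummy dummy scans before injection (metadata).
#' @param arrival_s bolus arrival time within the retained series (s).
#' @param r1_relaxivity Gd relaxivity (1/s/mM).
#' @param tr_s,flip_deg SPGR readout parameters.
#' @param keep_conc keep the true concentration array in the result.
#' @return A [dynamic_series()].
#' @export
simulate_dce <- function(maps, aif = aif_model(), dt_s = 5, n_frames = 50,
                         n_dummy = 40, arrival_s = 25, r1_relaxivity = 3.4,
                         tr_s = 0.039, flip_deg = 40, noise_sigma = 0,
                         seed = NULL, keep_conc = FALSE) {
  pm <- pull_maps(maps, c("pd", "t1_s", "ktrans_per_min", "ve"))
  stopifnot(dt_s > 0, n_frames >= 2, inherits(aif, "aif_model"))
  if (arrival_s < 0 || arrival_s > (n_frames - 1) * dt_s) {
    stop("bolus arrival must fall within the frame series")
  }
  kt <- pm$maps$ktrans_per_min
  ve <- pm$maps$ve
  if (any(kt > 0 & ve <= 0)) {
    stop("inconsistent tissue parameters: ktrans > 0 requires ve > 0 (finite kep)")
  }
  d <- dim(pm$maps$pd)
  times_s <- (seq_len(n_frames) - 1) * dt_s
  sig <- array(NA_real_, dim = c(d, n_frames))
  conc <- if (keep_conc) array(0, dim = c(d, n_frames)) else NULL
  kep <- ifelse(kt > 0, kt / ve, 0)
  with_seed(seed, {
    for (i in seq_len(n_frames)) {
      tau_min <- (times_s[i] - arrival_s) / 60
      ct <- tofts_conc_kernel(tau_min, kt, kep, aif)
      if (keep_conc) conc[, , , i] <- ct
      r1 <- 1 / pm$maps$t1_s + r1_relaxivity * ct
      s <- spgr_signal(pm$maps$pd, 1 / r1, flip_deg, tr_s)
      sig[, , , i] <- rician_noise(s, noise_sigma)
    }
  })
  dynamic_series(sig, dt_s = dt_s, n_dummy = n_dummy, arrival_s = arrival_s,
                 tr_s = tr_s, flip_deg = flip_deg,
                 r1_relaxivity = r1_relaxivity, aif = aif,
                 geometry = pm$geometry, conc = conc)
}
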