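# Dynamic contrast-enhanced analysis: bolus-arrival detection, SPGR
# signal-to-concentration conversion, the six semi-quantitative curve
# parameters, and the Tofts model (closed-form forward evaluation and
# bounded least-squares fitting).

# Closed-form Tofts concentration for a biexponential AIF, vectorized over
# voxels at one time point. tau_min is time since bolus arrival (minutes);
# negative tau gives 0. kep must equal ktrans/ve (precomputed by callers).
tofts_conc_kernel <- function(tau_min, ktrans, kep, aif) {
  if (length(tau_min) != 1) stop("tau_min must be scalar here")
  if (tau_min <= 0) return(ktrans * 0)
  term <- function(a, m) {
    dm <- m - kep
    near <- abs(dm) < 1e-9
    out <- a * (exp(-kep * tau_min) - exp(-m * tau_min)) /
      ifelse(near, 1, dm) # placeholder denominator where degenerate
    out[near] <- a * tau_min * exp(-m * tau_min)
    out
  }
  aif$dose_mmol_kg * ktrans *
    (term(aif$a1_kg_l, aif$m1_per_min) + term(aif$a2_kg_l, aif$m2_per_min))
}

#' Tofts-model tissue concentration (closed form)
#'
#' Evaluates `Ct(t) = Ktrans int_0^t Cp(u) exp(-kep (t - u)) du` for the
#' biexponential AIF using the exact biexponential solution
#' `Ct = Ktrans D sum_i a_i (exp(-kep tau) - exp(-m_i tau)) / (m_i - kep)`
#' with `tau` the time since bolus arrival; the removable singularity at
#' `m_i = kep` is evaluated by its limit. Concentration is 0 before
#' arrival.
#'
#' @param times_s frame times (s).
#' @param arrival_s bolus arrival time (s) on the same clock.
#' @param ktrans_per_min volume transfer constant (1/min).
#' @param ve extravascular-extracellular volume fraction; ignored when
#'   `ktrans_per_min = 0`.
#' @param aif an [aif_model()].
#' @return Tissue concentration (mM) at `times_s`.
#' @export
tofts_conc <- function(times_s, arrival_s, ktrans_per_min, ve, aif = aif_model()) {
  stopifnot(ktrans_per_min >= 0)
  if (ktrans_per_min == 0) return(rep(0, length(times_s)))
  stopifnot(ve > 0, ve <= 1)
  kep <- ktrans_per_min / ve
  tau <- (times_s - arrival_s) / 60
  term <- function(a, m) {
    dm <- m - kep
    if (abs(dm) < 1e-9) a * tau * exp(-m * tau)
    else a * (exp(-kep * tau) - exp(-m * tau)) / dm
  }
  ct <- aif$dose_mmol_kg * ktrans_per_min *
    (term(aif$a1_kg_l, aif$m1_per_min) + term(aif$a2_kg_l, aif$m2_per_min))
  ct[tau <= 0] <- 0
  ct
}

#' Detect bolus arrival in a dynamic curve
#'
#' Arrival is the first frame whose signal exceeds the running-baseline
#' mean plus `k_sd` baseline standard deviations for `min_consecutive`
#' consecutive frames; the baseline for a candidate frame is every frame
#' before it. At least `min_baseline` baseline frames are required before
#' the first candidate.
#'
#' @param x numeric signal or concentration curve (one value per frame).
#' @param k_sd threshold in baseline standard deviations (default 3).
#' @param min_consecutive consecutive supra-threshold frames required
#'   (default 2).
#' @param min_baseline minimum number of baseline frames (default 3).
#' @return List of class `bolus_arrival` with `arrival_index` (1-based
#'   frame index, `NA` when nothing qualifies: the explicit no-arrival
#'   result) and `no_arrival`.
#' @export
detect_bolus_arrival <- function(x, k_sd = 3, min_consecutive = 2,
                                 min_baseline = 3) {
  stopifnot(is.numeric(x), min_baseline >= 3, min_consecutive >= 1, k_sd >= 0)
  n <- length(x)
  if (n < min_baseline + min_consecutive) stop("curve too short for arrival detection")
  for (i in (min_baseline + 1L):(n - min_consecutive + 1L)) {
    bl <- x[seq_len(i - 1L)]
    thr <- mean(bl) + k_sd * stats::sd(bl)
    if (all(x[i:(i + min_consecutive - 1L)] > thr)) {
      return(structure(list(arrival_index = i, no_arrival = FALSE,
                            threshold = thr),
                       class = "bolus_arrival"))
    }
  }
  structure(list(arrival_index = NA_integer_, no_arrival = TRUE,
                 threshold = NA_real_),
            class = "bolus_arrival")
}

#' @export
print.bolus_arrival <- function(x, ...) {
  if (x$no_arrival) cat("bolus arrival: none detected\n")
  else cat(sprintf("bolus arrival at frame %d (0-based %d)\n",
                   x$arrival_index, x$arrival_index - 1L))
  invisible(x)
}

#' Construct a concentration curve
#'
#' @param times_s frame times (s), strictly increasing.
#' @param conc_mM Gd concentration per frame (mM).
#' @param arrival_index 1-based bolus-arrival frame index.
#' @param flags optional per-frame logical marking clipped/low-confidence
#'   frames.
#' @export
concentration_curve <- function(times_s, conc_mM, arrival_index,
                                flags = rep(FALSE, length(times_s))) {
  stopifnot(length(times_s) == length(conc_mM), all(diff(times_s) > 0),
            arrival_index >= 1, arrival_index <= length(times_s),
            all(is.finite(conc_mM)))
  structure(list(times_s = as.numeric(times_s), conc_mM = as.numeric(conc_mM),
                 arrival_index = as.integer(arrival_index),
                 flags = flags),
            class = "concentration_curve")
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf(
    "concentration curve: %d frames, arrival frame %d, peak %.4g mM%s\n",
    length(x$conc_mM), x$arrival_index, max(x$conc_mM),
    if (any(x$flags)) sprintf(" (%d flagged frames)", sum(x$flags)) else ""
  ))
  invisible(x)
}

#' Convert dynamic SPGR signal to Gd concentration
#'
#' Inverts the SPGR signal equation frame by frame. The equilibrium signal
#' is calibrated from the pre-arrival baseline frames together with the
#' measured pre-contrast T1; each frame's `E1 = exp(-TR R1)` then follows
#' from the signal ratio, and `C(t) = (R1(t) - 1/T1_0) / r1`. Pre-arrival
#' concentrations are forced to zero. Frames whose signal ratio leaves the
#' invertible range of the SPGR curve are clipped and flagged.
#'
#' @param signal numeric vector of dynamic signal (one ROI or voxel).
#' @param times_s frame times (s).
#' @param arrival_index 1-based bolus-arrival frame (baseline = frames
#'   before it).
#' @param t1_0_s pre-contrast T1 of the converted tissue (s).
#' @param r1_relaxivity contrast relaxivity (1/s/mM), default 3.4.
#' @param tr_s,flip_deg SPGR readout parameters.
#' @return A [concentration_curve()]; clipped frames are flagged and the
#'   attribute `low_confidence` is set when any frame was clipped.
#' @export
signal_to_concentration <- function(signal, times_s, arrival_index, t1_0_s,
                                    r1_relaxivity = 3.4, tr_s = 0.039,
                                    flip_deg = 40) {
  stopifnot(is.numeric(signal), length(signal) == length(times_s),
            arrival_index >= 2, t1_0_s > 0, r1_relaxivity > 0)
  a <- flip_deg * pi / 180
  e10 <- exp(-tr_s / t1_0_s)
  s_base <- mean(signal[seq_len(arrival_index - 1L)])
  if (s_base <= 0) stop("non-positive baseline signal; cannot calibrate conversion")
  m0 <- s_base * (1 - e10 * cos(a)) / (sin(a) * (1 - e10))
  u <- signal / (m0 * sin(a))
  e1 <- (1 - u) / (1 - u * cos(a))
  flags <- !is.finite(e1) | e1 <= 0 | e1 >= 1
  e1_clipped <- pmin(pmax(e1, 1e-12), 1 - 1e-12)
  e1_clipped[!is.finite(e1)] <- 1e-12
  r1 <- -log(e1_clipped) / tr_s
  conc <- (r1 - 1 / t1_0_s) / r1_relaxivity
  pre <- seq_len(arrival_index - 1L)
  conc[pre] <- 0
  flags[pre] <- FALSE
  curve <- concentration_curve(times_s, conc, arrival_index, flags)
  attr(curve, "low_confidence") <- any(flags)
  curve
}

#' Semi-quantitative DCE parameters
#'
#' The six curve descriptors, computed from a per-lesion concentration
#' curve:
#' * `auc`: sum of concentrations over all frames (mM);
#' * `iauc90`: sum of concentrations from arrival to 90 s after arrival;
#' * `wash_in_slope`: `(C_peak - C_arrival) / (t_peak - t_arrival)` (mM/s);
#' * `wash_out_slope`: OLS slope of the curve from the peak to the last
#'   frame (mM/s), sign preserved (positive slopes allowed);
#' * `time_to_peak_s`: time from arrival to the peak;
#' * `peak_mM`: curve maximum (ties broken to the earliest frame).
#'
#' The literal-sum convention for AUC/iAUC keeps units in mM;
#' `time_scaled = TRUE` switches both to trapezoidal integrals in mM*s.
#' A peak at the arrival frame leaves the wash-in slope without a value; a
#' peak at the last frame leaves the wash-out slope without a value.
#'
#' @param curve a [concentration_curve()].
#' @param time_scaled use trapezoidal, Delta-t-scaled integrals (mM*s)
#'   instead of literal sums (mM).
#' @return List of class `semiquant_params`; undefined entries are
#'   `no_value` results, see [print.mpmri_no_value()].
#' @export
compute_semiquant <- function(curve, time_scaled = FALSE) {
  stopifnot(inherits(curve, "concentration_curve"))
  tt <- curve$times_s
  cc <- curve$conc_mM
  n <- length(cc)
  ai <- curve$arrival_index
  peak_i <- which.max(cc) # earliest maximum
  peak <- cc[peak_i]
  ttp <- tt[peak_i] - tt[ai]

  trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  in_win <- tt >= tt[ai] & tt <= tt[ai] + 90
  if (time_scaled) {
    auc <- trapz(tt, cc)
    iauc <- if (sum(in_win) >= 2) trapz(tt[in_win], cc[in_win]) else 0
  } else {
    auc <- sum(cc)
    iauc <- sum(cc[in_win])
  }

  wash_in <- if (peak_i <= ai) {
    no_value("peak at the arrival frame; wash-in slope undefined")
  } else {
    (peak - cc[ai]) / (tt[peak_i] - tt[ai])
  }
  wash_out <- if (peak_i >= n) {
    no_value("peak at the last frame; wash-out regression undefined")
  } else {
    idx <- peak_i:n
    xs <- tt[idx] - mean(tt[idx])
    sum(xs * (cc[idx] - mean(cc[idx]))) / sum(xs^2)
  }

  structure(list(auc = auc, iauc90 = iauc, wash_in_slope = wash_in,
                 wash_out_slope = wash_out, time_to_peak_s = ttp,
                 peak_mM = peak, peak_index = peak_i,
                 time_scaled = time_scaled),
            class = "semiquant_params")
}

#' @export
print.semiquant_params <- function(x, ...) {
  unit <- if (x$time_scaled) "mM*s" else "mM"
  fmt <- function(v) if (is_no_value(v)) paste0("<no value: ", v$reason, ">") else sprintf("%.4g", v)
  cat(sprintf(paste0(
    "semi-quantitative DCE parameters:\n",
    "  AUC        %.4g %s\n  iAUC(90s)  %.4g %s\n  wash-in    %s mM/s\n",
    "  wash-out   %s mM/s\n  time-to-peak %.4g s\n  peak       %.4g mM\n"),
    x$auc, unit, x$iauc90, unit, fmt(x$wash_in_slope), fmt(x$wash_out_slope),
    x$time_to_peak_s, x$peak_mM))
  invisible(x)
}

#' Fit the Tofts model to a concentration curve
#'
#' Bounded nonlinear least squares of the closed-form Tofts solution (see
#' [tofts_conc()]) against the observed concentrations from the arrival
#' frame onward. `Ktrans` is bounded to [0, 5] 1/min and `ve` to
#' (0.01, 1]; fitting restarts from `n_starts` log-spaced `Ktrans` initial
#' values and keeps the lowest-RMSE converged solution. A curve that never
#' leaves zero returns `Ktrans = 0` with `ve` flagged unidentifiable.
#'
#' @param curve a [concentration_curve()].
#' @param aif the [aif_model()] the tissue curve is aligned to (same
#'   arrival).
#' @param bounds_ktrans,bounds_ve parameter bounds.
#' @param n_starts number of multistart initial values (default 5).
#' @return An object of class `tofts_fit` with `print`, `coef`, `predict`,
#'   `residuals` and `plot` methods. Fields: `ktrans_per_min`, `ve`,
#'   `kep_per_min`, `rmse`, `converged`, `identifiable`.
#' @export
fit_tofts <- function(curve, aif = aif_model(), bounds_ktrans = c(0, 5),
                      bounds_ve = c(0.01, 1), n_starts = 5) {
  stopifnot(inherits(curve, "concentration_curve"), inherits(aif, "aif_model"))
  tt <- curve$times_s
  cc <- curve$conc_mM
  ai <- curve$arrival_index
  idx <- ai:length(cc)
  if (length(idx) < 10) stop("need at least 10 post-arrival frames to fit the Tofts model")
  arrival_s <- tt[ai]

  if (max(abs(cc[idx])) < 1e-12) {
    fit <- structure(list(ktrans_per_min = 0, ve = NA_real_,
                          kep_per_min = NA_real_, rmse = 0, converged = TRUE,
                          identifiable = FALSE, curve = curve, aif = aif,
                          arrival_s = arrival_s),
                     class = "tofts_fit")
    return(fit)
  }

  obj <- function(par) {
    pred <- tofts_conc(tt[idx], arrival_s, par[1], par[2], aif)
    sum((pred - cc[idx])^2)
  }
  starts <- exp(seq(log(0.01), log(2), length.out = n_starts))
  starts <- pmin(pmax(starts, bounds_ktrans[1] + 1e-6), bounds_ktrans[2])
  best <- NULL
  any_conv <- FALSE
  for (k0 in starts) {
    res <- tryCatch(
      stats::optim(c(k0, 0.3), obj, method = "L-BFGS-B",
                   lower = c(bounds_ktrans[1], bounds_ve[1]),
                   upper = c(bounds_ktrans[2], bounds_ve[2]),
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    conv <- res$convergence == 0
    any_conv <- any_conv || conv
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("Tofts fit failed from every start")
  rmse <- sqrt(best$value / length(idx))
  structure(list(ktrans_per_min = best$par[1], ve = best$par[2],
                 kep_per_min = best$par[1] / best$par[2], rmse = rmse,
                 converged = any_conv, identifiable = TRUE,
                 curve = curve, aif = aif, arrival_s = arrival_s),
            class = "tofts_fit")
}

#' @export
print.tofts_fit <- function(x, ...) {
  cat(sprintf(
    "Tofts model fit: Ktrans %.4g /min, ve %s, kep %s /min (RMSE %.3g mM%s%s)\n",
    x$ktrans_per_min,
    if (is.na(x$ve)) "unidentifiable" else sprintf("%.3g", x$ve),
    if (is.na(x$kep_per_min)) "-" else sprintf("%.3g", x$kep_per_min),
    x$rmse,
    if (!x$converged) ", NOT converged" else "",
    if (!x$identifiable) ", flat curve" else ""
  ))
  invisible(x)
}

#' @export
coef.tofts_fit <- function(object, ...) {
  c(ktrans_per_min = object$ktrans_per_min, ve = object$ve,
    kep_per_min = object$kep_per_min)
}

#' @export
predict.tofts_fit <- function(object, times_s = NULL, ...) {
  if (is.null(times_s)) times_s <- object$curve$times_s
  if (!object$identifiable) return(rep(0, length(times_s)))
  tofts_conc(times_s, object$arrival_s, object$ktrans_per_min, object$ve,
             object$aif)
}

#' @export
residuals.tofts_fit <- function(object, ...) {
  object$curve$conc_mM - predict(object)
}

#' @export
plot.tofts_fit <- function(x, ...) {
  graphics::plot(x$curve$times_s, x$curve$conc_mM, pch = 16,
                 xlab = "time (s)", ylab = "Gd concentration (mM)", ...)
  tfine <- seq(min(x$curve$times_s), max(x$curve$times_s), length.out = 200)
  graphics::lines(tfine, predict(x, tfine), col = "firebrick", lwd = 2)
  graphics::abline(v = x$arrival_s, lty = 3)
  invisible(x)
}
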