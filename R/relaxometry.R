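# Variable-flip-angle T1 mapping (DESPOT1) and blood-normalized
# T2-weighted intensity.

#' Fit T1 maps from a variable-flip-angle SPGR series
#'
#' The default linearized DESPOT1 estimator regresses `y = S/sin(a)` on
#' `x = S/tan(a)` per voxel; the slope is `E1 = exp(-TR/T1)`, so
#' `T1 = -TR / log(slope)` and `M0 = intercept / (1 - E1)`. Voxels whose
#' slope falls outside (0, 1), or with fewer than 3 positive-signal
#' angles, are flagged unfittable. `method = "nls"` refines each DESPOT1
#' solution by nonlinear least squares on the SPGR equation itself
#' (Gauss-Newton).
#'
#' @param series a [vfa_series()].
#' @param mask optional logical array restricting the fit.
#' @param method `"despot1"` (default) or `"nls"`.
#' @return A `parameter_map` (quantity `t1_s`) whose diagnostics carry the
#'   `m0` map, per-voxel `r_squared`/`rss` and the QC table.
#' @export
fit_t1_vfa <- function(series, mask = NULL, method = c("despot1", "nls")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "vfa_series"))
  ang <- series$flip_angles_deg * pi / 180
  if (length(ang) < 3) stop("need at least 3 flip angles for a stable T1 fit")
  tr <- series$tr_s
  d <- dim(series$signal)[1:3]
  nvox <- prod(d)
  S <- matrix(series$signal, nrow = nvox, ncol = length(ang))
  if (is.null(mask)) mask <- rep(TRUE, nvox) else mask <- as.logical(mask)

  usable <- mask & rowSums(S <= 0) == 0
  t1 <- rep(NA_real_, nvox)
  m0 <- rep(NA_real_, nvox)
  r2 <- rep(NA_real_, nvox)
  rss <- rep(NA_real_, nvox)
  bad_slope <- rep(FALSE, nvox)

  if (any(usable)) {
    Su <- S[usable, , drop = FALSE]
    Y <- sweep(Su, 2, sin(ang), "/")
    X <- sweep(Su, 2, tan(ang), "/")
    xm <- rowMeans(X); ym <- rowMeans(Y)
    sxx <- rowSums((X - xm)^2)
    sxy <- rowSums((X - xm) * (Y - ym))
    slope <- sxy / sxx
    inter <- ym - slope * xm
    ok <- is.finite(slope) & slope > 0 & slope < 1
    t1_u <- ifelse(ok, -tr / log(slope), NA_real_)
    m0_u <- ifelse(ok, inter / (1 - slope), NA_real_)

    if (method == "nls") {
      for (j in which(ok)) {
        par <- c(m0_u[j], t1_u[j])
        y <- Su[j, ]
        for (it in 1:60) {
          e1 <- exp(-tr / par[2])
          den <- 1 - e1 * cos(ang)
          f <- par[1] * sin(ang) * (1 - e1) / den
          # df/dE1 via quotient rule, dE1/dT1 = e1 * tr / T1^2
          dfd_e1 <- par[1] * sin(ang) * (cos(ang) - 1) / den^2
          J <- cbind(f / par[1], dfd_e1 * e1 * tr / par[2]^2)
          r <- y - f
          step <- tryCatch(solve(crossprod(J) + diag(1e-14, 2), crossprod(J, r)),
                           error = function(e2) NULL)
          if (is.null(step)) break
          par <- par + as.vector(step)
          par[2] <- min(max(par[2], 1e-4), 100)
          if (max(abs(step) / pmax(abs(par), 1e-8)) < 1e-12) break
        }
        m0_u[j] <- par[1]; t1_u[j] <- par[2]
      }
    }

    e1f <- exp(-tr / t1_u)
    fit <- (m0_u * (1 - e1f)) * outer(rep(1, length(t1_u)), sin(ang)) /
      (1 - outer(e1f, cos(ang)))
    res <- Su - fit
    rss_u <- rowSums(res^2)
    tss <- rowSums((Su - rowMeans(Su))^2)

    idx <- which(usable)
    t1[idx] <- t1_u
    m0[idx] <- m0_u
    rss[idx] <- rss_u
    r2[idx] <- ifelse(tss > 0, 1 - rss_u / tss, 1)
    bad_slope[idx[!ok]] <- TRUE
  }

  fitted <- !is.na(t1)
  qc <- data.frame(
    voxel = c(which(mask & !usable), which(bad_slope)),
    reason = c(rep("fewer than 3 positive-signal angles", sum(mask & !usable)),
               rep("DESPOT1 slope outside (0, 1)", sum(bad_slope)))
  )
  parameter_map(
    quantity = "t1_s",
    values = array(t1, dim = d),
    geometry = series$geometry,
    fitted_mask = array(fitted, dim = d),
    diagnostics = list(m0 = array(m0, dim = d),
                       r_squared = array(r2, dim = d),
                       rss = array(rss, dim = d)),
    qc = qc, method = method
  )
}

#' Blood-normalized T2-weighted intensity
#'
#' Mean lesion intensity divided by mean reference-vessel intensity on the
#' same T2-weighted volume. The vessel ROI is an operator input (one
#' manually placed reference per imaging session); blood intensity is not
#' expected to change with age or treatment, which is what makes the ratio
#' comparable across sessions. The ratio is dimensionless and invariant to
#' global receiver gain.
#'
#' @param t2w a `t2w_image` (see [simulate_t2w()]) or 3D numeric array.
#' @param lesion_roi logical array or `lesion_roi` selecting lesion voxels.
#' @param vessel_roi logical array or `lesion_roi` selecting vessel voxels.
#' @return The normalized intensity (positive scalar).
#' @export
normalized_t2 <- function(t2w, lesion_roi, vessel_roi) {
  vol <- if (inherits(t2w, "t2w_image")) t2w$signal else t2w
  get_mask <- function(r) if (inherits(r, "lesion_roi")) r$mask else as.logical(r)
  lm_ <- get_mask(lesion_roi); vm_ <- get_mask(vessel_roi)
  if (!any(lm_)) stop("empty lesion ROI")
  if (!any(vm_)) stop("empty vessel ROI")
  v_mean <- mean(vol[vm_])
  if (v_mean <= 0) stop("reference vessel ROI has non-positive mean intensity")
  mean(vol[lm_]) / v_mean
}
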