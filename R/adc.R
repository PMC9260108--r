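# Mono-exponential ADC mapping from multi-b-value diffusion data.

#' Fit apparent diffusion coefficient maps
#'
#' Per-voxel mono-exponential fit of `S(b) = S0 exp(-b ADC)`. The default
#' `loglinear` method is ordinary least squares of `log S` on `-b`
#' (vectorized across voxels); `nls` minimizes squared error in the signal
#' domain (Gauss-Newton per voxel, initialized from the log-linear
#' solution) and is the better choice in the Rician-bias-sensitive regime.
#' No b = 0 image is required: `S0` is always an extrapolated fit
#' parameter.
#'
#' Fitted ADC values are clipped to [0, 0.01] mm^2/s; clipped voxels and
#' voxels excluded for non-positive signal are flagged in the QC table
#' rather than dropped silently.
#'
#' @param series a [diffusion_series()].
#' @param mask optional logical array of voxels to fit (default all).
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return A `parameter_map` (quantity `adc_mm2_s`) with `values`, `s0`,
#'   per-voxel `r_squared` and `rss` diagnostics, a `fitted_mask`, and a
#'   `qc` data frame of excluded or clipped voxels.
#' @export
fit_adc <- function(series, mask = NULL, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "diffusion_series"))
  b <- series$b_values
  d <- dim(series$signal)[1:3]
  nvox <- prod(d)
  S <- matrix(series$signal, nrow = nvox, ncol = length(b))
  if (is.null(mask)) mask <- rep(TRUE, nvox) else mask <- as.logical(mask)
  stopifnot(length(mask) == nvox)

  pos_all <- rowSums(S <= 0) == 0
  pos_low <- S[, 1] > 0
  usable <- mask & (if (method == "loglinear") pos_all else pos_low)

  adc <- rep(NA_real_, nvox)
  s0 <- rep(NA_real_, nvox)
  r2 <- rep(NA_real_, nvox)
  rss <- rep(NA_real_, nvox)

  if (any(usable)) {
    Su <- S[usable, , drop = FALSE]
    # log-domain OLS, vectorized: slope of log S on b
    L <- log(pmax(Su, .Machine$double.xmin))
    bc <- b - mean(b)
    denom <- sum(bc^2)
    slope <- as.vector(L %*% bc) / denom
    inter <- rowMeans(L) - slope * mean(b) # intercept = log S0
    adc_u <- -slope
    s0_u <- exp(inter)
    if (method == "nls") {
      for (j in seq_len(nrow(Su))) {
        y <- Su[j, ]
        par <- c(max(s0_u[j], 1e-12), max(adc_u[j], 0))
        for (it in 1:50) {
          e <- exp(-b * par[2])
          f <- par[1] * e
          r <- y - f
          J <- cbind(e, -par[1] * b * e)
          step <- tryCatch(solve(crossprod(J) + diag(1e-12, 2), crossprod(J, r)),
                           error = function(e2) NULL)
          if (is.null(step)) break
          par <- par + as.vector(step)
          par[1] <- max(par[1], 1e-12)
          if (max(abs(step)) < 1e-12 * max(1, max(abs(par)))) break
        }
        s0_u[j] <- par[1]
        adc_u[j] <- par[2]
      }
    }
    fit <- outer(s0_u, rep(1, length(b))) * exp(-outer(adc_u, b))
    res <- S[usable, , drop = FALSE] - fit
    rss_u <- rowSums(res^2)
    tss <- rowSums((Su - rowMeans(Su))^2)
    adc[usable] <- adc_u
    s0[usable] <- s0_u
    rss[usable] <- rss_u
    r2[usable] <- ifelse(tss > 0, 1 - rss_u / tss, 1)
  }

  out_of_range <- !is.na(adc) & (adc < 0 | adc > 0.01)
  adc_clipped <- pmin(pmax(adc, 0), 0.01)

  qc <- data.frame(
    voxel = c(which(mask & !usable), which(out_of_range)),
    reason = c(rep("non-positive signal", sum(mask & !usable)),
               rep("ADC outside [0, 0.01] mm^2/s (clipped)", sum(out_of_range)))
  )

  parameter_map(
    quantity = "adc_mm2_s",
    values = array(adc_clipped, dim = d),
    geometry = series$geometry,
    fitted_mask = array(usable, dim = d),
    diagnostics = list(r_squared = array(r2, dim = d),
                       rss = array(rss, dim = d),
                       s0 = array(s0, dim = d)),
    qc = qc, method = method
  )
}

#' Quantitative parameter map
#'
#' A 3D quantitative map with fixed units, per-voxel fit diagnostics and an
#' explicit mask of fitted voxels (non-fitted voxels are `NA` and flagged,
#' never silently zero).
#'
#' @param quantity one of `adc_mm2_s`, `t1_s`, `t2norm`, `ktrans_per_min`,
#'   `ve`, `conc_mM`.
#' @param values 3D numeric array.
#' @param geometry optional [acq_geometry()].
#' @param fitted_mask logical array marking voxels with a valid fit.
#' @param diagnostics list of per-voxel diagnostic arrays (R-squared,
#'   residual norms, auxiliary parameters).
#' @param qc data frame of flagged voxels and reasons.
#' @param method fitting method label.
#' @export
parameter_map <- function(quantity, values, geometry = NULL,
                          fitted_mask = NULL, diagnostics = list(),
                          qc = data.frame(), method = NA_character_) {
  quantity <- match.arg(quantity, c("adc_mm2_s", "t1_s", "t2norm",
                                    "ktrans_per_min", "ve", "conc_mM"))
  values <- as_3d(values)
  if (is.null(fitted_mask)) fitted_mask <- !is.na(values)
  structure(list(quantity = quantity, values = values, geometry = geometry,
                 fitted_mask = as_3d(fitted_mask), diagnostics = diagnostics,
                 qc = qc, method = method),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[x$fitted_mask]
  cat(sprintf(
    "parameter map (%s, %s): %d/%d voxels fitted, median %.4g [%.4g, %.4g]%s\n",
    x$quantity, x$method, sum(x$fitted_mask), length(x$fitted_mask),
    stats::median(v), min(v), max(v),
    if (nrow(x$qc)) sprintf("; %d QC-flagged voxels", nrow(x$qc)) else ""
  ))
  invisible(x)
}

#' Per-ROI summary of a parameter map
#'
#' Mean, sample standard deviation and voxel count of a fitted parameter
#' over an ROI; only voxels with a valid fit contribute, and the count is
#' reported so minimum-size rules stay auditable. An ROI with no fitted
#' voxels yields the explicit no-value result (`n_voxels = 0`, `NA`
#' statistics), never NaN arithmetic.
#'
#' @param map a [parameter_map()].
#' @param roi a `lesion_roi` or logical array matching the map.
#' @return List with `mean`, `sd` (sample, `NA` when `n_voxels < 2`) and
#'   `n_voxels`.
#' @export
roi_mean_adc <- function(map, roi) {
  stopifnot(inherits(map, "parameter_map"))
  mask <- if (inherits(roi, "lesion_roi")) roi$mask else as.logical(roi)
  mask <- as_3d(array(mask, dim = dim(map$values)))
  sel <- mask & map$fitted_mask & !is.na(map$values)
  n <- sum(sel)
  if (n == 0) {
    return(list(mean = NA_real_, sd = NA_real_, n_voxels = 0L,
                no_value = no_value("ROI contains no fitted voxels")))
  }
  v <- map$values[sel]
  list(mean = mean(v), sd = if (n >= 2) stats::sd(v) else NA_real_,
       n_voxels = as.integer(n))
}
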