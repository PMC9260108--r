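#' Tissue parameter set
#'
#' Ground-truth MR and pharmacokinetic parameters of one tissue class.
#' Units: proton density is arbitrary (signal scale), T1 in seconds, T2 in
#' milliseconds, ADC in mm^2/s, K-trans in 1/min, v_e dimensionless in (0, 1].
#'
#' @param pd proton density (> 0); TE decay of non-dynamic sequences may be
#'   folded into it.
#' @param t1_s longitudinal relaxation time (s).
#' @param t2_ms transverse relaxation time (ms).
#' @param adc_mm2_s apparent diffusion coefficient (mm^2/s).
#' @param ktrans_per_min volume transfer constant (1/min); 0 for
#'   non-enhancing tissue.
#' @param ve extravascular-extracellular volume fraction in (0, 1].
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(pd, t1_s, t2_ms, adc_mm2_s,
                          ktrans_per_min = 0, ve = 1) {
  stopifnot(
    pd > 0, t1_s > 0, t2_ms > 0, adc_mm2_s > 0,
    ktrans_per_min >= 0, ve > 0, ve <= 1
  )
  p <- list(
    pd = as.numeric(pd), t1_s = as.numeric(t1_s), t2_ms = as.numeric(t2_ms),
    adc_mm2_s = as.numeric(adc_mm2_s),
    ktrans_per_min = as.numeric(ktrans_per_min), ve = as.numeric(ve)
  )
  p$kep_per_min <- p$ktrans_per_min / p$ve
  stopifnot(is.finite(p$kep_per_min))
  class(p) <- "tissue_params"
  p
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(
    "tissue: pd %.3g, T1 %.3g s, T2 %.3g ms, ADC %.4g mm2/s, Ktrans %.3g /min, ve %.2f\n",
    x$pd, x$t1_s, x$t2_ms, x$adc_mm2_s, x$ktrans_per_min, x$ve
  ))
  invisible(x)
}

#' Default tissue library
#'
#' Representative parameter sets for the tissue classes of the renal-lesion
#' phantom at high field. Lesion ADCs straddle the classification thresholds
#' (cystic above 0.0022 mm^2/s, papillary at/below 0.0012); K-trans spans the
#' 0.04 (poorly perfused, cystic) to 0.33 1/min (permeable, solid) range; the
#' blood-vessel reference has low effective proton density (FSE flow
#' attenuation), which puts blood-normalized T2 intensity of cystic lesions
#' near 10. Values are package defaults, overridable per phantom.
#'
#' @return Named list of [tissue_params()]: `background`, `parenchyma`,
#'   `cystic`, `papillary`, `solid`, `vessel`.
#' @export
tissue_library <- function() {
  list(
    background = tissue_params(pd = 0.02, t1_s = 1.0, t2_ms = 5,
                               adc_mm2_s = 1e-4, ktrans_per_min = 0, ve = 1),
    parenchyma = tissue_params(pd = 1.0, t1_s = 1.7, t2_ms = 32,
                               adc_mm2_s = 0.0015, ktrans_per_min = 0.25, ve = 0.3),
    cystic     = tissue_params(pd = 1.05, t1_s = 3.2, t2_ms = 90,
                               adc_mm2_s = 0.0028, ktrans_per_min = 0.04, ve = 0.3),
    papillary  = tissue_params(pd = 1.0, t1_s = 2.6, t2_ms = 45,
                               adc_mm2_s = 0.0011, ktrans_per_min = 0.15, ve = 0.25),
    solid      = tissue_params(pd = 1.0, t1_s = 2.8, t2_ms = 40,
                               adc_mm2_s = 0.0016, ktrans_per_min = 0.33, ve = 0.3),
    vessel     = tissue_params(pd = 0.15, t1_s = 2.2, t2_ms = 20,
                               adc_mm2_s = 0.003, ktrans_per_min = 0, ve = 1)
  )
}

#' Biexponential arterial input function
#'
#' Population plasma curve `Cp(t) = D (a1 exp(-m1 t) + a2 exp(-m2 t))` for
#' `t >= 0` after bolus arrival and 0 before. The default amplitudes and
#' decay rates are the classic population parametrization compatible with
#' rodent Gd-DTPA kinetics; the dose is 0.27 mmol/kg. With `a` in kg/L and
#' `D` in mmol/kg, `Cp` is in mM.
#'
#' @param dose_mmol_kg injected dose (mmol/kg).
#' @param a1_kg_l,a2_kg_l amplitudes (kg/L).
#' @param m1_per_min,m2_per_min decay rates (1/min).
#' @return An object of class `aif_model`.
#' @export
aif_model <- function(dose_mmol_kg = 0.27, a1_kg_l = 3.99, a2_kg_l = 4.78,
                      m1_per_min = 0.144, m2_per_min = 0.0111) {
  stopifnot(dose_mmol_kg > 0, a1_kg_l > 0, a2_kg_l > 0,
            m1_per_min > 0, m2_per_min > 0)
  a <- list(dose_mmol_kg = dose_mmol_kg, a1_kg_l = a1_kg_l, a2_kg_l = a2_kg_l,
            m1_per_min = m1_per_min, m2_per_min = m2_per_min)
  class(a) <- "aif_model"
  a
}

#' Plasma concentration of an AIF
#'
#' @param aif an [aif_model()].
#' @param t_min time after bolus arrival (minutes); values `< 0` give 0.
#' @return Plasma Gd concentration (mM), same length as `t_min`.
#' @export
aif_plasma_conc <- function(aif, t_min) {
  stopifnot(inherits(aif, "aif_model"))
  cp <- aif$dose_mmol_kg * (aif$a1_kg_l * exp(-aif$m1_per_min * t_min) +
                            aif$a2_kg_l * exp(-aif$m2_per_min * t_min))
  cp[t_min < 0] <- 0
  cp
}

#' @export
print.aif_model <- function(x, ...) {
  cat(sprintf(
    "biexponential AIF: dose %.3g mmol/kg, a = (%.3g, %.3g) kg/L, m = (%.3g, %.3g) /min\n",
    x$dose_mmol_kg, x$a1_kg_l, x$a2_kg_l, x$m1_per_min, x$m2_per_min
  ))
  invisible(x)
}

#' Ellipsoidal lesion specification
#'
#' One ground-truth lesion: an ellipsoid in world (mm) coordinates with a
#' tissue class and its parameters. Analytic volume is `4/3 pi prod(radii)`.
#'
#' @param lesion_id positive integer identifier; also the deterministic
#'   priority when lesions overlap (lower id wins).
#' @param center_mm ellipsoid centre, length-3 (mm).
#' @param radii_mm ellipsoid semi-axes, length-3 (mm), all positive.
#' @param tissue_class one of `"cystic"`, `"papillary"`, `"solid"`.
#' @param params a [tissue_params()]; defaults to the [tissue_library()]
#'   entry for `tissue_class`.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(lesion_id, center_mm, radii_mm,
                        tissue_class = c("cystic", "papillary", "solid"),
                        params = NULL) {
  tissue_class <- match.arg(tissue_class)
  stopifnot(length(center_mm) == 3, length(radii_mm) == 3, all(radii_mm > 0),
            lesion_id == as.integer(lesion_id), lesion_id > 0)
  if (is.null(params)) params <- tissue_library()[[tissue_class]]
  stopifnot(inherits(params, "tissue_params"))
  l <- list(
    lesion_id = as.integer(lesion_id),
    center_mm = as.numeric(center_mm),
    radii_mm = as.numeric(radii_mm),
    tissue_class = tissue_class,
    params = params
  )
  l$volume_mm3 <- 4 / 3 * pi * prod(l$radii_mm)
  class(l) <- "lesion_spec"
  l
}

#' @export
print.lesion_spec <- function(x, ...) {
  cat(sprintf(
    "lesion %d (%s): centre (%.2f, %.2f, %.2f) mm, radii (%.3f, %.3f, %.3f) mm, V = %.4g mm3\n",
    x$lesion_id, x$tissue_class, x$center_mm[1], x$center_mm[2], x$center_mm[3],
    x$radii_mm[1], x$radii_mm[2], x$radii_mm[3], x$volume_mm3
  ))
  invisible(x)
}
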