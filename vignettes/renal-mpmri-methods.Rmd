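---
title: "Multiparametric MRI of renal lesions: models, simulators and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric MRI of renal lesions: models, simulators and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalmpmri)
```

## Scope and design

`renalmpmri` implements the quantitative analysis chain used to
characterize and monitor renal lesions (cystadenomas and
angiomyolipoma-like tumors of tuberous sclerosis complex) with
multiparametric ^1^H MRI in a preclinical setting: ADC mapping from
multi-b-value diffusion imaging, variable-flip-angle (VFA/DESPOT1) T1
mapping, blood-normalized T2-weighted intensity, semi-quantitative and
Tofts-model DCE quantification, slice-geometry-aware lesion volumetry
with Bland-Altman agreement, and longitudinal response metrics. Because
no in-vivo dataset ships with the package, a digital phantom generator
produces ground-truth lesions and simulates all four acquisitions, so
every estimator can be validated by round-trip parameter recovery.

Each estimator follows the classic R modelling idiom: a fitting function
returning a classed object (`parameter_map` for the voxelwise maps,
`tofts_fit` with `print`/`coef`/`predict`/`residuals`/`plot` methods for
the pharmacokinetic fit), with base-R internals.

## The phantom

A virtual animal consists of two ellipsoidal kidneys, a midline
reference vessel and a lesion population on a 30 x 30 mm field of view.
Per animal, the lesion count is drawn from Normal(36, 5.7) truncated at
one, and lesion volumes are log-uniform over 0.016-5.12 mm^3^ — the
count and size range observed in 6-7-month-old animals of this model.
The log-uniform choice reflects that only the range and mean of sizes
are known, with small lesions dominating; no size distribution is
otherwise established. Tissue classes (cystic / papillary / solid, at
probabilities 0.61 / 0.18 / 0.21 following the histological proportions
in untreated animals) carry distinct T1, T2, ADC, K^trans^ and v~e~
values chosen so that cystic lesions sit above the 0.0022 mm^2^/s ADC
threshold, papillary lesions at or below 0.0012, and K^trans^ spans the
0.04-0.33 min^-1^ range between poorly perfused cystic and permeable
solid lesions. The reference vessel is given a low effective proton
density (fast-spin-echo flow attenuation), which places blood-normalized
T2 intensity of lesions near 10, the magnitude observed in vivo.

Rasterization computes, per voxel, the lesion volume fraction by 4x
per-axis supersampling (64 subsamples per voxel); voxel parameters are
the volume-fraction-weighted mixture of lesion and underlying tissue.
Overlapping lesions are resolved deterministically in `lesion_id` order.
For the smallest lesions of the study (0.016 mm^3^ at 0.117 mm in-plane
/ 0.5 mm slices) the default supersampling reproduces the analytic
ellipsoid volume to about 4%; `supersample = 8` brings it inside 2% and
is what the accuracy tests use at that size.

## Forward models

* **Diffusion**: `S(b) = pd exp(-b ADC)` at b = 25, 180, 323, 508
  s/mm^2^.
* **SPGR/VFA**: `S = pd sin a (1 - E1)/(1 - E1 cos a)`,
  `E1 = exp(-TR/T1)`, at flip angles 2-40 degrees and TR 39 ms; echo-time
  decay is folded into `pd` (constant across angles).
* **T2-weighted FSE**: `S = pd (1 - exp(-TR/T1)) exp(-TE/T2)` at TE
  10 ms, TR 3 s; the saturation term is what differentiates 2D (TR 3 s)
  from 3D (TR 200 ms) SNR.
* **DCE**: the standard Tofts model
  `Ct(t) = Ktrans \int_0^t Cp(u) e^{-kep (t-u)} du` driven by a
  population biexponential plasma curve
  `Cp(t) = D (a1 e^{-m1 t} + a2 e^{-m2 t})` with D = 0.27 mmol/kg,
  a = (3.99, 4.78) kg/L, m = (0.144, 0.0111) min^-1^. The convolution is
  evaluated with its exact biexponential closed form (the removable
  singularity at `kep = m_i` uses the analytic limit); the test suite
  verifies it against trapezoidal numerical convolution on a 0.1 s grid.
  The dynamic signal applies `R1(t) = 1/T1_0 + r1 Ct(t)` inside the SPGR
  equation, with Gd-DTPA relaxivity r1 = 3.4 s^-1^mM^-1^ (high-field
  regime), at 5 s resolution over 50 frames.

Noise is Rician on magnitude images (the magnitude of the signal plus
complex Gaussian noise), with the scale expressed as a reference tissue
signal divided by a target SNR. All simulators are bit-reproducible
under a fixed seed, and the pipeline derives one named substream per
stage from the single study seed.

The acquisition protocol states a DCE in-plane resolution that is
inconsistent with its own FOV/matrix pair; the package always derives
voxel size as FOV/matrix and ignores separately quoted resolutions.

## Estimators and numerical choices

**ADC.** The default fit is ordinary least squares of `log S` on `-b`,
vectorized across voxels; S0 is always an extrapolated parameter (no
b = 0 image is acquired). A signal-domain Gauss-Newton (`method =
"nls"`) is provided for the Rician-bias-sensitive regime. ADC is
clipped to [0, 0.01] mm^2^/s; clipped voxels and voxels with
non-positive signal are flagged in a QC table, never silently dropped.
ROI summaries report the sample (n-1) standard deviation and the voxel
count so minimum-size rules stay auditable.

**T1.** DESPOT1: regress `S/sin a` on `S/tan a`; the slope is E1, so
`T1 = -TR/log(slope)` and `M0 = intercept/(1 - E1)`. Slopes outside
(0, 1) are unfittable and flagged. The linearization is exact on
noiseless data (round trips agree with truth to ~1e-15) and a
Gauss-Newton refinement of the SPGR equation itself is available; the
two agree well inside 0.5% noiseless.

**Bolus arrival.** No detection rule is established for this protocol,
so the package uses a running-baseline threshold: the first frame
exceeding the baseline mean plus 3 baseline standard deviations for 2
consecutive frames, with the baseline being all earlier frames (at
least 3). On simulated series at SNR 20 this lands within one frame of
the true arrival in over 95% of replicates. A curve that never
qualifies returns an explicit no-arrival result.

**Signal-to-concentration.** The SPGR equation is inverted exactly:
the equilibrium signal is calibrated from the pre-arrival baseline and
the measured pre-contrast T1 (T1 maps are acquired immediately before
injection, which is what makes this inversion possible), each frame's
E1 follows from the signal ratio, and
`C = (R1 - 1/T1_0)/r1`. Frames whose ratio leaves the invertible range
are clipped and flagged, and pre-arrival concentrations are forced to
zero. No hematocrit correction is applied by default: the AIF is
treated as a plasma curve, and the dose parameter is configurable.

**Semi-quantitative DCE.** AUC and iAUC(90 s) are literal sums of
concentrations (units mM), matching the stated definition; a
trapezoidal, Delta-t-scaled variant (mM s) sits behind
`time_scaled = TRUE` since the unit convention is not otherwise fixed.
Time-to-peak is measured from bolus arrival; peak ties break to the
earliest frame. A peak at the arrival frame leaves wash-in undefined, a
peak at the last frame leaves wash-out undefined — both return explicit
no-value results.

**Tofts fit.** Bounded least squares (L-BFGS-B) of the closed-form
solution, K^trans^ in [0, 5] min^-1^ and v~e~ in (0.01, 1], with five
log-spaced K^trans^ starts and the best-RMSE winner; the convergence
flag is honest and a flat curve returns K^trans^ = 0 with v~e~ flagged
unidentifiable. Noiseless end-to-end recovery (simulate, convert, fit)
is inside 0.1%; at SNR 20 the median K^trans^ error is a few percent
and the 0.04-vs-0.33 min^-1^ ordering is essentially always preserved.

**Volumetry and the rater model.** ROI volume is voxel count times
in-plane voxel area times slice thickness — linear in thickness and
additive over disjoint ROIs. The rater emulation `digitize_lesion`
includes a pixel when the fraction of the pixel covered by the lesion's
*projection through the slice slab* reaches the threshold (default
0.5). The projection — rather than the 3D volume fraction — is what an
observer sees on a slice image: a thin lesion still shows its full
in-plane extent on a thick slice, which is precisely the mechanism of
partial-volume overestimation. Consequences worth knowing: digitized
volumes overestimate small lesions, the 1 mm-vs-0.5 mm overestimation
ratio is larger for lesions below 0.25 mm^3^ than above 1 mm^3^ (the
direction seen in vivo), and convergence to the analytic volume is
first-order in voxel size, so a residual of a few tenths remains at
0.25 mm slices. The threshold is the lever controlling the
overestimation; human raters are not otherwise reproducible.

**Agreement statistics.** Bland-Altman uses the sample (n-1) standard
deviation and the fixed 1.96 multiplier; zero variance in either list
makes the Pearson correlation an explicit no-value while the bias is
still returned. Pearson p-values are two-sided on the t distribution.

**Longitudinal metrics.** Percent change is `100 (X_w - X_0)/X_0`, per
lesion or per animal total (lesion volumes summed first); zero or
missing baselines drop the series with a count, never imputation.
Per-lesion trends are OLS slopes per day with a mean +/- SE group
summary; the per-lesion table is exported for external mixed-model
software, which is deliberately out of scope here. ADC classification:
cystic above 0.0022 mm^2^/s; papillary at or below 0.0012 (the cited
papillary value, since no explicit papillary cutoff is established —
the default is exposed in configuration and flagged in reports);
boundaries go to the lower class.

## The longitudinal cohort generator

`simulate_cohort` emulates two groups of three animals imaged weekly
for three weeks. Group-mean volume trajectories are +28/+62/+71%
(control) and +36/+39/+39% (treated) from baseline; normalized-T2
slopes are -0.1058 (control) and +0.0841 (treated) per day; T1 slopes
+0.0276 / -0.0058 s/day. ADC slopes are not reported numerically in
vivo, only their directions, so the generator uses +1.9e-5 mm^2^/s/day
(treated: from 1.9e-3 to about 2.3e-3 over 21 days) and -2e-6
(control). The printed dispersions of the percent changes are placed at
the *lesion* level, as a per-lesion random effect shared across weeks
(smooth trajectories), with no separate animal random effect: with
three animals per group the two levels cannot be distinguished anyway,
and the lesion-level placement makes group summaries estimable from the
~100 lesions per group. Group summaries of a seeded cohort recover the
generator's signs and ordering (control grows faster than treated;
treated normalized-T2 rises while control falls) in well over 95% of
replicates.

## What the phantom does and does not show

The phantom reproduces the study's statistical structure (lesion
counts, sizes, classes, acquisition parameters, group effects) and
exact forward models, so green tests demonstrate that the estimators
invert their models correctly and degrade gracefully under Rician
noise. It does not simulate k-space or reconstruction, motion or
respiratory artifacts, B1 inhomogeneity, fat signal, or raters'
perceptual variability; agreement with the phantom therefore does not
by itself establish accuracy on in-vivo data, where those effects are
present. Statistical group testing (repeated-measures ANOVA, mixed
models) is exported-data territory, not reimplemented.

## Problem sizes

The test suite and the acceptance script use: single-voxel series for
closed-form checks; 10^4^ voxels for noisy ADC/T1 recovery; 500
replicates for K^trans^ recovery at SNR 20; 1000 replicates for
arrival detection; 100 random datasets for the agreement property; 25
lesions per size class for the partial-volume comparison at full
256 x 256 in-plane resolution; 40 seeded cohorts for the longitudinal
ordering property and 8 for the reported summaries. Full-volume
pipeline runs use scaled matrices (the `scale` argument of
`default_study_config`), which changes voxel size but none of the
lesion statistics.
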