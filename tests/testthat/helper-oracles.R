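# Shared fixtures and independent oracles. Oracles here deliberately avoid
# the package's own closed forms: convolution is numerical, agreement
# statistics are recomputed from first principles.

# Single-voxel parameter maps for forward-model tests.
tiny_maps <- function(pd = 1, t1_s = 2.97, t2_ms = 40, adc = 0.0019,
                      ktrans = 0.33, ve = 0.3, n = 1) {
  list(
    pd = array(pd, c(n, 1, 1)), t1_s = array(t1_s, c(n, 1, 1)),
    t2_ms = array(t2_ms, c(n, 1, 1)), adc_mm2_s = array(adc, c(n, 1, 1)),
    ktrans_per_min = array(ktrans, c(n, 1, 1)), ve = array(ve, c(n, 1, 1))
  )
}

# Numerical Tofts convolution: trapezoidal integration of
# Ktrans * Cp(u) * exp(-kep (t - u)) on a fine grid (independent of the
# package's closed form).
tofts_conc_numeric <- function(times_s, arrival_s, ktrans, ve, aif,
                               grid_s = 0.1) {
  kep <- ktrans / ve
  vapply(times_s, function(t) {
    if (t <= arrival_s) return(0)
    u <- seq(0, (t - arrival_s) / 60, by = grid_s / 60)
    cp <- aif_plasma_conc(aif, u)
    y <- cp * exp(-kep * ((t - arrival_s) / 60 - u))
    ktrans * sum(diff(u) * (head(y, -1) + tail(y, -1)) / 2)
  }, numeric(1))
}

# First-principles Bland-Altman / Pearson recomputation.
bland_altman_brute <- function(a, b) {
  d <- a - b
  n <- length(d)
  bias <- sum(d) / n
  sdd <- sqrt(sum((d - bias)^2) / (n - 1))
  am <- sum(a) / n; bm <- sum(b) / n
  r <- sum((a - am) * (b - bm)) /
    sqrt(sum((a - am)^2) * sum((b - bm)^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tt), df = n - 2)
  list(bias = bias, loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
       r = r, p = p)
}

# The piecewise-linear concentration fixture: zero for frames 0-2, linear
# rise from arrival (frame index 3, 0-based; t = 15 s) to 1 mM at t = 65 s,
# then linear fall to 0.5 mM at t = 245 s.
piecewise_curve <- function() {
  tt <- (0:49) * 5
  cc <- numeric(50)
  rise <- tt >= 15 & tt <= 65
  fall <- tt > 65
  cc[rise] <- (tt[rise] - 15) / 50
  cc[fall] <- 1 - (tt[fall] - 65) / 360
  concentration_curve(tt, cc, arrival_index = 4L)
}
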