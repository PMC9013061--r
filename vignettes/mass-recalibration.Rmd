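---
title: "Endogenous-reference mass recalibration for DESI-MSI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endogenous-reference mass recalibration for DESI-MSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msirecal)
```

## The model

A DESI-MSI dataset is a sequence of N centroided spectra, one per pixel,
acquired continuously over hours. We assume the instrument's calibration
state varies *smoothly* with acquisition time, for which the pixel order is
a proxy. Two statistical models act at different scales:

**Per-reference drift trend.** For a reference ion of theoretical mass
$M$, matched at pixels $p_i$ with observed masses $M^{\#}_i$, the trend is a
Gaussian additive model

$$M^{\#}_i \sim \mathrm{Normal}(\eta_i, \sigma^2), \qquad
  \eta_i = \beta_0 + \sum_{j=1}^{20} s_j(p_i)$$

with penalized cubic regression splines $s_j$. The smoothing penalty is
selected by GCV over eleven values log-spaced in $[10^{-3}, 10^3]$. The
fitted trend predicts the observed mass of the reference at *every* ROI
pixel, including pixels where it was not detected — this is what makes a
global reference set usable despite tissue heterogeneity.

**Per-pixel calibration.** Given the trend-predicted observed masses
$\hat M_k$ and theoretical masses $M^*_k$ of the accepted references, each
pixel gets its own calibration map: for Orbitrap a linear model
$M^* = \beta_0 + \beta_1 \hat M$ (orbital-trap mass error is very nearly a
relative offset), for TOF a polynomial in the square-root domain
$\sqrt{M^*} = \beta_0 + \sum_{d=1}^{D} \beta_d (\sqrt{\hat M})^d$, because
TOF measures flight time $\propto \sqrt{m/z}$. The degree $D \le 5$
minimises $\mathrm{BIC} = n\log(\mathrm{RSS}/n) + (D+1)\log n$; degrees
with fewer than $D+2$ supporting references are not considered.

## Isolating drift tracks

Within a search window (W = 20 ppm Orbitrap / 100 ppm TOF) a candidate
reference collects true matches, noise matches, and sometimes a second,
interfering peak. The track filter works in the (pixel order, observed m/z)
plane, both axes scaled to $[0,1]$:

1. A 2D KDE with triangular kernel $K(u) = 1-|u|$ on a $1024 \times 1024$
   grid, bandwidth $h = 2.576\,\sigma N^{-1/5}$ with $\sigma$ the SD of the
   pooled scaled coordinates.
2. The ridge: in each grid column the y-argmax (ties to the smaller y;
   all-zero columns skipped), mapped back to (pixel, m/z).
3. A cubic smoothing spline through the ridge; its penalty is chosen by
   fivefold CV over 30 values log-spaced in $[10^{-5}, 0.1]$ with a fixed
   fold seed recorded in the fit.
4. Outliers: $r_i = |M^{\#}_i - S(p_i)| \ge 2 \cdot \mathrm{mad}(r)$, one
   pass. The $r_i$ are already absolute deviations about the spline, so
   $\mathrm{mad}(r) = 1.4826 \cdot \mathrm{median}(r)$ — a robust estimate
   of the noise SD, making the cut a classic two-sigma rule. Centering the
   MAD a second time (at the median of the $r_i$) would flag ~27% of a
   perfectly clean Gaussian track and no reference could ever reach the 75%
   inlier-coverage requirement at realistic detection rates; we consider
   the single-centered form the only self-consistent reading and use it.
   When $\mathrm{mad} = 0$ only strictly positive residuals are flagged, so
   perfect tracks are kept whole.
5. Acceptance: distinct inlier pixels $\ge$ 75% of the ROI *and* dispersion
   $d_i = 2\,\mathrm{mad}(r)\,/\,S(p_i) \times 10^6 \le 10$ ppm (computed
   on post-filter residuals, so it reflects the cleaned track). The 10 ppm
   ceiling is a user-adjustable reflection of expected measurement noise.

When two tracks ~15 ppm apart cannot be separated at the KDE bandwidth
(large drift spreads the y-axis, so 15 ppm is small after scaling), the
merged cloud inflates the dispersion and the candidate is rejected; when
the bandwidth resolves them, the ridge locks onto the denser track and the
interferent is removed as outliers. Both behaviours are exercised in the
test suite with a planted two-track fixture.

## Numerical choices

* **Exact FFT KDE.** The kernel is implemented as the separable product
  triangular kernel $(1-|x|)(1-|y|)$ — the 2D form of $K$ is not uniquely
  pinned down by its 1D definition, and the product form is the cheaper
  one. It is piecewise *bilinear*, so if the bandwidth is an integer number
  of grid cells, linear binning followed by a zero-padded FFT convolution
  is algebraically identical to the direct double sum over points. We
  therefore snap $h$ to the nearest grid cell ($\le 0.05\%$ perturbation at
  G = 1024) and the FFT estimate agrees with a brute-force evaluation to
  machine precision (~1e-15), not merely to a binning tolerance.
* **Ridge spline parametrisation.** The smoothing grid $[10^{-5}, 0.1]$ is
  applied to `stats::smooth.spline`'s $\lambda$; near the lower end the
  spline approaches interpolation of the ridge, near the upper end a
  near-linear fit. CV folds are assigned randomly with a fixed seed stored
  in the result, so refits are reproducible.
* **GAM basis.** `mgcv` absorbs one identifiability constraint into the
  basis, so `s(p, bs = "cr", k = 20)` plus the intercept realises the
  20-term penalized cubic spline model. The penalty grid is scanned with
  fixed `sp` per fit and the smallest GCV wins (no continuous
  optimisation, keeping the selection reproducible across mgcv versions).
* **Common-error filter.** Per pixel, relative errors
  $e_k = (\hat M_k - M^*_k)/M^*_k \times 10^6$ are filtered to the
  dominant mode of a 1D triangular-kernel KDE (band ±2.5 ppm Orbitrap /
  ±10 ppm TOF; mode ties resolve to the lower ppm). If fewer than two
  references survive, the unfiltered set is used with a warning — a pixel
  must still be recalibrated.
* **Degenerate inputs.** Zero-variance point sets floor the bandwidth at
  machine epsilon with a warning; all-zero KDE columns yield no ridge
  point; fewer than 5 ridge points discard the reference; a degenerate
  per-pixel design (all predictions equal) leaves the pixel uncorrected
  and flagged; TOF predictions that go non-positive in the sqrt domain
  leave the affected peak unchanged and flagged.
* **Extrapolation.** Per-pixel models are evaluated as-is outside the
  reference-covered m/z range, and that range is recorded per pixel. With
  high BIC-selected degrees, extrapolated corrections far outside the
  covered range can be poor — the references bound the trustworthy region.

## The synthetic-data generator

`simulate_dataset()` stands in for real acquisitions with known ground
truth. It emulates: smooth sinusoidal pixel-order drift (multiplicative in
ppm for Orbitrap; modulated by a quadratic polynomial in scaled
$\sqrt{m/z}$ for TOF, normalised so the stated amplitude is attained);
ppm-scale Gaussian measurement noise; per-reference Bernoulli detection;
log-normal intensities; decoy interferents at fixed ppm offsets detected
over a contiguous block of *image columns* (raster scanning interleaves a
spatial region across acquisition order, which is how real complementary
tissue regions present); and off-sample pixels carrying only background
peaks. Everything derives from one mandatory seed, and simulation is
bit-reproducible.

The defaults define the package's study conditions: a 50 × 50 grid with
2,000 ROI pixels, 20 reference ions spanning 227–886 m/z, 5 ppm drift with
0.5 ppm noise (Orbitrap) or 60 ppm drift with 3 ppm noise (TOF), detection
probability 0.9, drift period two-thirds of the acquisition. These sizes
keep a full pipeline run around a minute while leaving every stage's
statistics well-populated; the drift period and the TOF mass-curvature
weights (0.4, 0.2, 0.4) were fixed once as plausible shapes for a
several-hour acquisition.

What the generator does *not* emulate: profile peak shapes (only
centroids), chemical noise beyond uniform decoys, intensity-dependent mass
errors, isotope structure, or spatial correlation of detection. Passing
tests therefore demonstrate correct recovery of smooth pixel-order drift
under idealised matching conditions, not performance on the full
complexity of real tissue data.

## Evaluation semantics

The improvement statistic $\tilde\Delta$ is the median over pixels of the
per-pixel median of paired differences $|e^{\mathrm{before}}| -
|e^{\mathrm{after}}|$ on held-out test masses ("median of differences",
matching the bootstrap's single per-pixel quantity; the alternative
"difference of medians" reading is not used). The bootstrap resamples
pixels with replacement; the two-sided p-value is twice the fraction of
bootstrap medians contradicting the observed sign, clipped to $[2/B, 1]$.
Under a simulated null this test holds its nominal size to within the
tolerance the suite asserts (5% ± 2% at $\alpha = 0.05$).

One accounting subtlety: a recalibrated peak retains its own measurement
noise. With 3 ppm noise, a *perfect* correction still leaves a median
absolute error of $0.674 \times 3 \approx 2$ ppm. The scoring function
therefore separates the systematic residual (what calibration can control,
computed against the ground truth's noise-free drifted positions) from the
irreducible noise, and reports both.

## Limitations

* Acquisition order is taken to be imzML storage order; an explicit order
  vector can be supplied when that assumption fails.
* Only processed-mode (per-pixel centroid) imzML is supported.
* Off-ROI pixels are passed through uncorrected.
* The TOF preprocessing chain (kneedle threshold, Savitzky–Golay,
  centroiding) implements the canonical forms of those operations with all
  parameters exposed; centroided public datasets bypass it entirely.
* References concentrated in part of the m/z range leave the rest to
  polynomial extrapolation; inspect the recorded per-pixel coverage range
  before trusting corrections far outside it.
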