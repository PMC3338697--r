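---
title: "Quantifying membrane-protein oligomerization from single confocal images"
author: "oligofluct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-protein oligomerization from single confocal images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligofluct)
```

## The measurement problem

Membrane transporters and receptors sit in the plasma membrane as monomers,
dimers and higher oligomers whose footprint is far below the diffraction
limit, so a conventional fluorescence image cannot resolve the oligomeric
state directly. What a single confocal (CLSM) image *does* carry is the
statistics of its spatial intensity fluctuations: a field of dim, dense
monomers and a field of half as many twice-as-bright dimers have the same
mean intensity but different fluctuation amplitudes. `oligofluct` implements
the two complementary spatial-fluctuation analyses that exploit this —
higher-order image moment analysis and spatial intensity distribution
analysis (SpIDA, the fitting of the pixel-intensity histogram with a
super-Poissonian model) — together with the detector calibration both
require and a synthetic-image simulator that provides ground truth for
validation.

Both techniques work on a *single* fixed image, which is what makes them
applicable to chemically fixed cells and native tissue sections where
temporal fluctuation methods (FCS, N&B, PCH) are unavailable.

## Model

Fluorescent entities ("n-mers": monomers, dimers, ...) are modeled as a
spatial Poisson process in the membrane plane. Each entity carries a quantal
brightness $\epsilon$ (detector intensity units, iu — the peak pixel
intensity one entity contributes when centered on a pixel); absent
quenching, a fully labeled dimer has $2\epsilon_{\text{monomer}}$. The
microscope blurs each point emitter with a Gaussian beam profile
$g(r) = e^{-2r^2/\omega_0^2}$, where $\omega_0$ is the $e^{-2}$ radius.
Densities are expressed per *beam area*
$BA = \int g\, dA = \pi\omega_0^2/2$, the convention under which the mean
image intensity is exactly

$$\langle I \rangle = N_1\epsilon_1 + N_2\epsilon_2$$

for two populations with $N_i$ entities per beam area.

### Moment analysis

For a compound Poisson field the spatial cumulants of the pixel intensities
are additive over populations:

$$\kappa_n = \gamma_n \left(N_1\epsilon_1^n + N_2\epsilon_2^n\right),
  \qquad \gamma_n = \frac{\int g^n dA}{\int g\, dA} = \frac{1}{n}$$

($\gamma_n = 1/n$ for the 2D Gaussian profile; `shape_factor()` documents
and tests this against numerical quadrature). One population is solved from
the first two cumulants ($\epsilon = \kappa_2/(\gamma_2\langle I\rangle)$,
$N = \langle I\rangle/\epsilon$); two populations from the first four. The
package inverts the four-cumulant system exactly by the classical method of
moments (Prony): the reduced moments $a_n = \kappa_n/\gamma_n$ are power
sums of a two-point mass distribution, so $\epsilon_{1,2}$ are the roots of
a quadratic assembled from a 2×2 Hankel system. On noisy cumulants a damped
least-squares refinement in log-parameter space runs from a multistart grid
(brightness ratios 1.5–8 crossed with monomer- and oligomer-heavy splits),
and the fit falls back to the one-population solution when a second
population does not reduce the residual by at least a factor of four
(`accept_ratio = 0.25`).

### SpIDA

The pixel-intensity histogram of a one-population field is the compound
Poisson distribution

$$H(k) = \sum_n \mathrm{Pois}(n;\lambda)\, \rho^{*n}(k),$$

where $\rho(k)$ is the intensity a single particle at a uniformly random
position (within a disc of radius $3\omega_0$; the profile beyond is below
$2\times10^{-8}$ of peak) contributes to the central pixel, and $\lambda$
is the expected particle count in that disc. Because the Gaussian profile
is analytically invertible, $\rho$ is computed in closed form as exact
area fractions of the disc; a grid-sampled construction is retained as an
independent cross-check. Two coexisting populations convolve:
$H = H_1 * H_2$. Fitting the (detector-broadened) model to the observed
histogram by least squares recovers $(N, \epsilon)$ — or $(N_1, N_2)$ for a
monomer–dimer mixture with $\epsilon_2 = 2\epsilon_1$ tied and
$\epsilon_1$ fixed from an independent monomeric control, which is how the
two-population analysis is meant to be run in practice.

**Numerical construction.** The compound distribution is evaluated by
characteristic-function multiplication on an FFT grid (or by a direct
Poisson-weighted convolution sum for expected counts $\lambda \le 30$; both
routes agree to $10^{-8}$ and are cross-checked in the tests). Internally
the grid is 1/8 iu fine rather than integer: a pixel's value is the
*rounded sum* of many sub-unit contributions from distant particles, and a
model built directly on integer bins discards those tails, which biases the
whole histogram visibly at high density. The residual mean deficit of
quantizing the single-particle profile is restored as an intensity offset,
exactly $N\epsilon - \lambda m_1 \delta$; because that offset is linear in
$N$, Poisson superposition (`compound_histogram(N1 + N2) =
compound_histogram(N1) * compound_histogram(N2)`) remains exact to
$10^{-8}$, which the suite asserts.

### Detector calibration and correction

Analog PMTs report an intensity whose variance grows linearly with the mean
signal. The calibration (`fit_detector_noise()`) fits
$\mathrm{Var} = c + sI$ to mean/variance pairs from a uniform-illumination
point scan, using only the initial part of the curve: the fitted range is
extended point by point while $R^2 \ge 0.99$ and the newest residual stays
under 3 residual standard errors. The intercept $c$ (dark-noise variance)
is left free — a real PMT has dark noise, and $c \approx 0$ recovers the
through-origin case.

Given the law, the cumulants of the underlying noise-free field follow from
$M = I + \eta$, $\eta \mid I \sim \mathcal N(0,\, c + sI)$, whose cumulant
generating function is $K_M(t) = ct^2/2 + K_I(t + st^2/2)$:

$$\kappa_2 = \mu_2 - (c + s\langle I\rangle), \qquad
  \kappa_3 = \mu_3 - 3s\kappa_2, \qquad
  \kappa_4 = (\mu_4 - 3\mu_2^2) - 6s\kappa_3 - 3s^2\kappa_2,$$

with $\mu_n$ the measured central moments. The suite verifies over 50
simulated images that correcting after the simulated detector reproduces
the noise-free cumulants within Monte-Carlo error. For SpIDA the same law
enters as histogram *broadening*: each model mass at intensity $k$ is
redistributed as a discretized Gaussian of variance $c + sk$ (mass at or
below zero folds into bin 0; total mass is preserved to $10^{-9}$). When
the histogram is background-subtracted, the optional `offset` argument puts
the background back into the variance law, since the detector saw signal
plus background.

### MEU normalization

Brightnesses are only comparable within one set of imaging conditions, so
all results are expressed in monomeric equivalent units: the mean
brightness of a known-monomeric control sample (per-cell mean ± SEM,
`build_monomer_control()`) defines 1 MEU, and `normalize_to_meu()` divides
by it with first-order error propagation in quadrature. Calibrations carry
an `acquisition_tag` and refuse to normalize measurements from a different
tag. A monolayer-dye control's surface density versus solution
concentration is fitted with the saturating exponential
$D(c) = D_{\max}(1 - e^{-c/c_0})$ — saturating because surface binding is
sterically limited at high concentration, linear with slope $D_{\max}/c_0$
at low concentration.

## The simulator

`simulate_image()` is the ground-truth generator used by every validation:
Poisson-placed entities (with a guard margin of $3\omega_0$ beyond the
image border so edge pixels are unbiased), per-subunit binomial labeling,
exact Gaussian-profile rendering at continuous positions (evaluated at
pixel centers — the enforced oversampling $\text{pixel} < \omega_0$ makes
within-pixel integration unnecessary), then conditionally Gaussian detector
noise, clamping and integer rounding. Output is bit-identical for a fixed
seed. `simulate_bleach_series()` removes each fluorophore independently
with probability $1-s$ before every frame, so frame $i$ has expected
density $s^i$ of the initial value at unchanged quantal brightness — the
signature that distinguishes density loss from brightness loss.

Defaults emulate a 60×/1.4 NA confocal at 488 nm: $\omega_0 = 0.2$ µm,
pixel 0.046 µm, monomeric brightness 44 iu (the scale of a typical
antibody-label control under these conditions), detector slope 0.5 iu with
2 iu² dark variance, 16-bit full scale, 10 iu uniform background.

What the simulator does *not* emulate: spatial heterogeneity of real cells
(expression gradients, vesicles, membrane folds), fluorophore blinking and
quenching, partial antibody occupancy beyond the simple binomial
`label_fraction`, axial (z) structure, and scan-speed-dependent dwell
effects. Passing tests therefore demonstrate correctness of the estimators
under the model's assumptions, not robustness to every feature of real
tissue; on real images the tile-based sampling (`tile_moments()`, which
discards tiles whose mean deviates more than 50% from the median tile) is
the first defense against heterogeneity.

## Validation sizes and numerical choices

The test-suite problem sizes are chosen to keep the full run within a few
minutes while leaving comfortable statistical margins: 512² images for
brightness-ratio and density-ladder checks (20 and 10 seeds per condition),
1024² for model-versus-empirical histogram comparisons, 256² with 50 seeds
for the detector-correction identity. Bin width is fixed at 1 iu (the
detector's own quantization); the fit window defaults to the 99.9th
percentile of the observed histogram; fits are unweighted least squares on
normalized histograms (a Poisson-weighted option exists but is off by
default); optimization is in log-parameter space, which enforces
positivity without constraints, initialized from the one-population moment
inversion of the same histogram.

Degenerate inputs are handled explicitly: corrected $\kappa_2 \le 0$ flags
over-correction (mean outside the detector's linear range) rather than
returning imaginary brightnesses; empty fields give a point-mass histogram
at zero; a second population with vanishing density collapses to the
one-population result; saturated pixels above 1% of an ROI exclude the top
bin with a warning.

## Known limitations

* The free four-cumulant two-population inversion is exact on noise-free
  cumulants but amplifies sampling error in $\kappa_3$ and $\kappa_4$
  roughly fifteen-fold into the recovered densities; with ten 512² images
  the densities carry ~±25% statistical uncertainty even with the
  brightness ratio fixed. For quantitative mixture densities the SpIDA
  monomer–dimer fit with the monomeric brightness fixed from the control is
  the recommended (and much better conditioned) pipeline; the cumulant
  route is best used for the brightness ratio and as a cross-check.
* At most two populations are resolved; higher oligomers contribute to the
  recovered brightness but are not separated.
* The detector model is linear analog; photon-counting detectors,
  afterpulsing and nonlinearity beyond the hard `linear_max` cutoff are out
  of scope.
* Bleaching during a single scan is assumed negligible (single-image
  methods); the bleach-series simulator exists to validate that property,
  not to correct for it.

## A worked example

```{r example, eval = FALSE}
psf <- psf_model(e2_radius = 0.2, pixel_size = 0.046)
det <- detector_model(slope = 0.5, intercept = 2)

# simulate a pure-dimer field at 3 entities per beam area
spec <- simulation_spec(512, psf,
                        population_spec(3 / psf$beam_area,
                                        oligomer_order = 2,
                                        per_subunit_brightness = 44),
                        background = 10, detector = det, seed = 1)
sim <- simulate_image(spec)

# SpIDA one-population fit
obs <- image_to_histogram(sim$image, background = 10)
fit <- fit_histogram(obs, "one_pop", psf, det, background_offset = 10)
fit$estimates                       # eps near 88 iu, N near 3 per BA

# express against a monomeric control
cal <- build_monomer_control(c(43.4, 44.6, 44.1, 43.9, 44.3))
normalize_to_meu(fit$estimates[["eps"]], fit$stderr[["eps"]], cal)
```
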