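---
title: "Probabilistic hotspot mapping of MSI data: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic hotspot mapping of MSI data: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotmap)
```

## The problem

An ion image renders the summed intensity of all peaks inside a user-chosen
mass interval around a peak of interest. That convention ignores two things:
the resolving power of the instrument varies nonlinearly with m/z, so a fixed
interval is too wide at one end of the mass range and too narrow at the other;
and the rendered image carries no notion of statistical significance, so
"this metabolite accumulates here" rests on visual judgment. `spotmap`
addresses both: the mass window adapts to the measured peak width at the
metabolite's m/z, and the spatial pattern of intensities is tested pixel by
pixel against an explicit spatial null model.

## Data-dependent Gaussian mass-window weighting

Peak width is modeled from data. From one (or more) full-profile single-pixel
spectra, every peak with signal-to-noise ratio of at least 3 contributes a
measured FWHM (half-maximum flank crossings found by linear interpolation),
and a LOESS fit of FWHM against m/z gives a smooth, strictly positive
estimate of the instrument peak width at any m/z
(`extract_fwhm_points()`, `fit_fwhm_curve()`). The noise level behind the SNR
threshold is the median absolute deviation of the profile intensities (scaled
to be consistent with a normal distribution); the estimator is a design
choice — any reasonable robust scale estimate leads to the same accepted
peak set on clean profiles.

For a metabolite of interest (MOI) with theoretical m/z \(m_{MOI}\), a
Gaussian envelope is erected at \(m_{MOI}\) with
\(\sigma_G = \mathrm{FWHM}(m_{MOI}) / (2\sqrt{2\ln 2})\) and support
\(m_{MOI} \pm 3\sigma_G\). Every observed centroid inside the support
contributes its intensity weighted by the envelope value at its m/z
(1 at the center, \(e^{-2}\) at two envelope widths, 0 outside the support),
so proximal interfering signals are down-weighted smoothly rather than
either fully counted or fully ignored. The per-pixel weighted sums become
the marks of a spatial point pattern whose window is the union of all
measured pixels.

Tunable parameters, with defaults:

| parameter | default | units | role |
|---|---|---|---|
| `snr_min` | 3 | – | profile peaks accepted for FWHM measurement |
| LOESS `span` | 0.5 | fraction | smoothness of the FWHM(m/z) fit (degree-2 local polynomials) |
| window half-width | \(3\sigma_G\) | Da | effective support of the weighting envelope |
| `min_pixel_frac` | 0.01 | fraction | occurrence filter: peaks in fewer pixels are dropped |
| binning `tolerance` | 12 ppm | relative | iterative-bisecting bin criterion; 12 ppm = FWHM(400)/400 for a 0.0048 Da width, appropriate for lipids |
| `alpha` | 0.05 | – | significance level of both map tails |
| bandwidth grid | 1–10 by 0.5 | pixels | Moran's I scan for KDE bandwidth |

The closed-form resolution models (`theoretical_fwhm()`: the FTICR
low-pressure limit \(\Delta m = 7.589\,m^2/(qBT_{FID})\), the
collision-damped form \(\Delta m = 2\sqrt3\,m^2/(qB\tau)\), and the TOF
relation \(\Delta m = 2m\Delta t/t\)) are provided for qualitative
comparison only; the measured LOESS curve is authoritative in the pipeline.
The unit system of the FTICR constants is left to the caller to supply
consistently — the functions assert only the scaling laws (quadratic in
mass, inverse in charge), which the tests verify.

## The spatial null model and the probabilistic map

The marked point pattern \(SPP_{MOI}\) lives in the tissue window
\(\Phi_{tissue}\) (a union of unit pixel squares; area = pixel count) with
point density \(\Lambda = n/A_{tissue}\). Its intrinsic control is a
complete-spatial-randomness (CSR) model: exactly \(n\) points placed
uniformly in the window, carrying a random permutation of the original
marks. Fixing the count at exactly \(n\) (a binomial process rather than a
Poisson-random count) keeps the mark permutation one-to-one; the difference
is immaterial at the point counts involved and makes every CSR draw carry
precisely the observed mark multiset.

Both patterns are smoothed with an isotropic Gaussian kernel of standard
deviation \(h\) pixels, weighted by the marks, evaluated at pixel centers,
edge-corrected, and sum-normalized into density surfaces \(\rho_{MOI}\) and
\(\rho_{CSR}\). Edge handling is uniform correction: at every pixel the
kernel mass is renormalized by its integral inside the window (midpoint
rule on the pixel grid). Without it, boundary pixels of both surfaces are
biased low; with it, a uniform pattern yields an essentially flat surface
up to the window edge.

By the central limit theorem the CSR surface's pixel-value distribution
approaches a normal as \(h\) grows, and the package tests verify the
Kolmogorov–Smirnov distance to normality shrinks with increasing
bandwidth. With \(\mu_{CSR}\) and \(\sigma_{CSR}\) the mean and standard
deviation of the CSR surface over tissue pixels, each tissue pixel of
\(\rho_{MOI}\) receives an upper-tail p-value
\(P_{upr} = 1 - \Phi((\rho - \mu_{CSR})/\sigma_{CSR})\) and a lower-tail
\(P_{lwr} = \Phi(\cdot)\). Benjamini–Hochberg correction is applied within
each tail map separately, over tissue pixels only (pixels outside the
tissue are not part of the testing family). Pixels with corrected
upper-tail (lower-tail) p-values at or below \(\alpha\) form the hotspot
(coldspot) mask; marching-squares contouring at level 0.5 on the
zero-padded mask traces closed polygons, holes included, without any
smoothing of the traces. The null moments come from a single CSR
realization, whose seed is recorded in the result; the redraw variability
this introduces is measured directly by `stability_scan()` (mean
mask overlap across 20 redraws ≈ 0.99 on the ring simulation).

### Bandwidth selection

Too small a bandwidth leaves pixel noise in the surfaces; too large a one
smears away real structure. The bandwidth is chosen where spatial
autocorrelation stops improving: global Moran's I (first-order queen
adjacency, unit weights, tissue pixels only) is computed on the density at
each bandwidth of the 1–10 px grid (0.5 steps), and the knee of the
I-versus-bandwidth curve is found by the Kneedle construction — the
maximizer of the difference between the min-max-normalized curve and the
normalized bandwidth axis, at sensitivity 1. On a concave curve like
\(I(h) = 1 - e^{-h}\) sampled on this grid, that maximizer sits near
\(h \approx 3\) (the tests pin it against an independently computed
difference-curve oracle). If no knee stands out (a near-linear curve), the
fallback takes the largest bandwidth whose Moran's I increment still
exceeds 1% of the curve's range, with a warning. On the simulated ring
pattern, the Dice overlap between hotspot mask and ground truth peaks at
the grid value adjacent to the selected knee, which is the behavior the
selection is designed for.

## Cross-tissue comparison and ensemble projection

`compute_ctmpm()` rejects a pixel only when two independent nulls fail:
the spatial null of the test tissue's own map, and the intensity null that
the point's mark could have been drawn from the reference tissue's mark
distribution. The latter uses empirical-CDF tail probabilities with the
add-one estimator \((1 + \#\{r \ge x\})/(n_{ref}+1)\), so no p-value is
exactly zero, BH-corrected across test points (correcting per point rather
than per pixel is a design choice; the two coincide when each pixel holds
one point, the MSI case). Intensities of the two tissues must be
comparable — same slide or robust normalization — which the function can
only warn about, not verify.

`compute_cppm()` projects an ensemble of patterns onto one plane. Members
with duplicate observed m/z (multiple database matches of one peak)
contribute once — first in input order wins, deterministically. Each
retained member is z-score standardized (sample sd) to level out
ionization-efficiency differences; members with fewer than two points or
constant marks are skipped with a warning. Co-located points are kept
distinct, never summed. Because standardized marks can be negative while
the weighted density requires nonnegative marks, the projected marks are
shifted by their global minimum plus a small epsilon just before density
estimation; the shift is recorded in the result and never touches the
stored pattern. This convention is ours — how the original formulation
feeds signed standardized marks into a weighted density is not specified —
and a rank-preserving affine shift is the least structured choice: it
leaves the spatial arrangement and the mark ordering untouched.

Spatial arithmetic (`eval_expression()`) evaluates +, −, ×, ÷ over
rasterized patterns pixel by pixel; a pixel missing in any operand, or hit
by division by zero, is dropped, and the result returns to point-pattern
form for mapping. Division amplifies relative uncertainty, so using ÷
triggers a warning; no error propagation is attempted beyond that.

## What the synthetic generator does and does not emulate

`ground_truth_pattern()` and `simulate_pattern()` reproduce the validation
geometry: a 100×100-unit window; high-abundance regions shaped as a
central circle, five circles, a ring (outer/inner radii 30/20), or a
dominant circle with four small satellites (radii 20 and 5, area ratio
16); homogeneous Poisson point placement at 0.4 points per unit area
inside the high region and 0.3 outside; and marks whose high/background
mean ratio is 2.3. Since the empirical tissue intensities behind that
ratio are not shipped, marks default to lognormal draws (sdlog 0.5,
background mean 2000 counts — an FTICR-like scale consistent with
mean intensities far above 1000) with the high-region log-mean offset by
log 2.3, preserving positivity, skew, and the stated ratio; any
user-supplied sampler can replace it. The five-circle and satellite
placements (radius 10 at diagonal distance 30; satellites at diagonal
distance 30) are package choices where the geometry was not fully
specified, and are parameterized.

What the generator does **not** emulate: the heavy upper tail of real
FTICR intensity distributions, pixel-to-pixel and section-to-section batch
effects, mass miscalibration, and spatially correlated background. Passing
tests on these simulations therefore demonstrate the statistical machinery
(type-I control, ground-truth recovery, bandwidth selection, CSR-redraw
stability), not instrument-level robustness.

### Noise-injection robustness: what the simulation can and cannot show

The noise injectors reproduce three contamination types: per-signal
Gaussian noise with mean \(\mu_{MOI}\) and sd \(\sigma_k\)
(\(\sigma_0 = \sqrt{\mu_{MOI}}\), Poisson-like; \(\sigma_k = k\,\sigma_{MOI}\)
otherwise, clipped at zero), an interfering peak column at
\(m_{MOI} + 2\sigma_G\), and single-pixel artifacts of
Uniform(max, 10·max) magnitude. On the simulated ring, interference
robustness holds exactly as designed: the Gaussian window down-weights a
\(2\sigma_G\) interferent by \(e^{-2}\), and its mean squared error
against the clean image beats uniform weighting in ≥95% of seeded runs.

The mask-overlap robustness under heavy artifact and Gaussian
contamination, however, is intrinsically limited by the simulation's
contrast. The hotspot z-score of the ring over the CSR null is about 9 at
the knee bandwidth, set by the prescribed density ratio (0.4/0.3) and mean
mark ratio (2.3). Contamination enters the null through the permuted
marks, inflating \(\sigma_{CSR}\) by roughly
\(\sqrt{\lambda E[m^2]/(4\pi h^2)}\): Uniform(max, 10·max) artifacts in 2%
of pixels inflate it about sevenfold (ring z ≈ 1.3, mask empties, and the
artifact pixels themselves surface as small false hotspots), and k = 4
Gaussian mark noise about threefold (z ≈ 3.3, the mask shrinks to its
core, clean-vs-noisy Dice ≈ 0.3–0.4). Real-tissue hotspots with stronger
contrast retain their masks under the same contamination; the simulation
at the prescribed 2.3× contrast does not have that headroom, and the
package reports the degraded values rather than recalibrating the
simulation to mask them. At milder severities the simulated maps are
robust (Poisson-like noise k = 0: Dice ≈ 0.77; k = 1: ≈ 0.70).

## Numerical choices

- KDE is evaluated exactly (separable Gaussian factorization into two
  matrix products), not by binning or FFT approximation; tests pin it to a
  brute-force double loop at 1e−6.
- Iterative bisecting splits at the first (lowest-mass) occurrence of the
  maximal gap, making bins deterministic under ties; bin membership within
  a pixel is summed downstream, consistent with the weighting's summation.
- Zero-intensity pixels belong to the window but not to the point set; an
  MOI absent everywhere yields a valid empty pattern with a warning.
- All-zero pixels pass through TIC/RMS normalization unchanged, with a
  warning, rather than producing NaNs.
- imzML is written with float64 m/z and float32 intensities (the common
  dialect) and read back at stored precision; continuous-mode files are
  rejected with an instruction to centroid first.
- Every stochastic step takes an explicit seed and restores the caller's
  RNG state, so identical configurations give byte-identical exports.

## Problem sizes

The validation suite runs entirely on synthetic data: 100×100-pixel
windows with ~3000 points for the mapping checks (50 CSR seeds for type-I
control, 10 seeds for each contamination scan, 20 CSR redraws for
stability), 20×20 fixtures for the exact-oracle comparisons, and
60-peak synthetic profile spectra for the FWHM model. These sizes give
Monte-Carlo error well inside the asserted tolerances while keeping the
whole suite fast on a single CPU.

## Known limitations

- The pixel is the unit of inference; no cluster-level correction is
  applied, and kernels are isotropic and global (no adaptive bandwidth).
- The normal null is an approximation that improves with bandwidth; at
  h = 1 on sparse patterns it is rough, which is one reason the bandwidth
  scan starts there rather than below.
- Cross-tissue conclusions are only as good as the intensity
  comparability between tissues; the package warns but cannot enforce it.
- Mass miscalibration defeats the Gaussian window (a shifted peak is
  down-weighted as if it were an interferent); recalibration must happen
  upstream.
- Multiple acquisition regions in one imzML file are not separated
  automatically; callers supply a region mask by subsetting the peak
  matrix.
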