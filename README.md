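# spotmap

Probabilistic spatial mapping of metabolites in mass spectrometry imaging
(MSI).

## The problem

MALDI-MSI renders a metabolite as an ion image: the summed intensity of all
peaks inside a user-chosen m/z interval, per pixel. Two things are missing
from that convention. First, the interval ignores the instrument's resolving
power, which varies nonlinearly with m/z, so nearby interfering peaks are
either fully counted or fully cut off. Second, an ion image says nothing
about whether an apparent accumulation of signal is statistically
distinguishable from randomness. `spotmap` is for MSI users — biologists and
mass spectrometrists alike — who want both questions answered by the data:
a mass window whose shape follows the measured peak width, and maps in which
"hotspot" and "coldspot" are outcomes of a significance test rather than of
color-scale perception.

## The method

**Gaussian mass-window weighting.** From a full-profile single-pixel
spectrum, the FWHM of every peak with SNR ≥ 3 is measured and a LOESS fit
yields FWHM(m/z). For a metabolite of interest at theoretical m/z
*m*<sub>MOI</sub>, a Gaussian envelope with
σ<sub>G</sub> = FWHM(*m*<sub>MOI</sub>) / (2√(2 ln 2)) and support
*m*<sub>MOI</sub> ± 3σ<sub>G</sub> weights every observed centroid in the
support by exp(−(*m*<sub>j</sub> − *m*<sub>MOI</sub>)² / 2σ<sub>G</sub>²).
The per-pixel weighted sums become the marks of a spatial point pattern in
the tissue window Φ<sub>tissue</sub>.

**Molecular probabilistic maps (MPM).** The pattern's null model is complete
spatial randomness: the same number of points placed uniformly in
Φ<sub>tissue</sub>, carrying a random permutation of the marks. Both
patterns are smoothed by intensity-weighted Gaussian kernel density
estimation (bandwidth chosen at the knee of the Moran's I vs bandwidth
curve, Kneedle method), edge-corrected and sum-normalized. With
μ<sub>CSR</sub>, σ<sub>CSR</sub> the moments of the null surface, every
tissue pixel gets two-tail p-values
P<sub>upr</sub> = 1 − Φ((ρ − μ<sub>CSR</sub>)/σ<sub>CSR</sub>) and
P<sub>lwr</sub> = Φ(·), each tail Benjamini–Hochberg corrected; pixels with
corrected p ≤ α = 0.05 form hotspot/coldspot masks, traced into contour
polygons.

On top of single-MOI maps the package provides cross-tissue comparisons
(CT-MPM: spatial test in the test tissue ∧ per-point eCDF intensity test
against a reference tissue), collective projections of metabolite ensembles
(CPPM: z-standardized patterns projected onto one plane and mapped
together), and pixel-wise spatial arithmetic (e.g. the adenylate energy
charge (ATP + 0.5 ADP)/(ATP + ADP + AMP)).

A full synthetic validation suite ships with the package: ground-truth
hotspot geometries, Poisson point placement, lognormal marks, Gaussian /
interference / single-pixel-artifact noise injection, and Dice-coefficient
evaluation.

## Worked example

Simulate the ring-shaped ground-truth pattern (outer/inner radii 30/20 in a
100×100 window, point densities 0.4/0.3, mean intensity ratio 2.3) and map
it:

```r
library(spotmap)

gt  <- ground_truth_pattern("ring")
sim <- simulate_pattern(gt, seed = 11)
print(sim$spp)
#> Marked spatial point pattern: n = 3031 points, window 100 x 100 px (area 10000), lambda = 0.3031
#>   marks: min 216.2, median 2008, max 2.073e+04

scan <- estimate_bandwidth(sim$spp)
scan$knee
#> [1] 2.5

res <- compute_mpm(sim$spp, alpha = 0.05, h = scan$knee, seed = 5)
print(res)
#> Molecular probabilistic map: n = 3031 points, bandwidth 2.50 px, alpha = 0.05
#>   hotspot pixels: 1395 (1 contour(s)); coldspot pixels: 0 (0 contour(s))

dice(res$hotspot_mask, gt$truth_mask)
#> [1] 0.818
```

The map declares 1395 of 10000 pixels significantly abundant (one closed
contour) and none significantly deficient; the hotspot mask overlaps the
true ring (area ≈ 1571 px) with a Dice coefficient of 0.82. `export_mpm()`
writes the density and p-value grids, a GeoJSON of the contours, a rendered
PNG and a JSON sidecar; `render_map()` draws hotspot boundaries red/white
and coldspot boundaries blue/white.

For real data, the same pipeline starts from files:

```r
res <- run_mpm(imzml = "tissue.imzML", profile_csv = "profile.csv",
               mz = 544.3009, out_dir = "out", seed = 1)
```

where the Gaussian window at m/z 544.3009 for an FWHM of 0.0048 Da has
σ<sub>G</sub> = 0.002038 Da and support [544.2948, 544.3070]. METASPACE
annotation exports are read with `read_annotations()` (FDR-filtered), and a
thin command-line front end lives at `inst/cli/spotmap.R`
(`mpm`, `simulate`, `fwhm`, `evaluate` subcommands).

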