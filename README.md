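# flimstorm

Quantitative analysis of amyloid-beta aggregation in live-cell imaging data:
fluorescence-lifetime (FLIM/TCSPC) decay fitting, dSTORM single-molecule
localization and aggregate morphometry, and aggregation-kinetics statistics —
with seeded photon-level simulators for every input, so the entire pipeline
is testable without microscope data.

## The problem

An environment-sensitive dye conjugated to the amyloid-beta peptide reports
incorporation into beta-sheet amyloid through a drop in its fluorescence
lifetime (roughly 3.7 ns for the monomeric conjugate, 3.3 ns and below for
fibrillar material). Imaging that lifetime per pixel turns aggregation state
into a quantity that can be followed non-invasively in living cells, and
super-resolution imaging of the same aggregates gives their sizes and
shapes. This package is for researchers who need the full analysis chain
behind such experiments:

* **FLIM**: per-pixel fits of `F(t) = A · (IRF ⊛ e^(−t/τ)) + B` to TCSPC
  photon-arrival histograms (Poisson MLE by default, Neyman least squares
  optionally), adaptive sliding-window binning to a 3500–5000 photons/pixel
  target, lifetime maps, per-pixel lifetime histograms, and two-level
  region summaries (mean ± SEM across images).
* **dSTORM**: per-frame local-maximum detection, Poisson-weighted Gaussian
  PSF fitting, localization precision by the Thompson closed form
  `σ² = s²/N + a²/(12N) + 8πs⁴b²/(a²N²)`, density-histogram rendering, and a
  resolution estimate combining precision FWHM with the Nyquist sampling
  limit.
* **Morphometry**: 8-connected segmentation of rendered images, aggregate
  sizing by pixel counting along the longest dimension (Feret diameter plus
  one-bin end cap), aspect ratios, a resolution-limit filter, and size
  summaries per condition.
* **Kinetics & statistics**: sigmoid fits
  `L(t) = L∞ + (L0 − L∞)/(1 + e^{k(t−t50)})` with lag phase `t50 − 2/k`
  (clamped at zero), half-time offsets between paired readouts, paired
  Student t tests and protected Fisher LSD comparisons.
* **Simulators**: TCSPC decay cubes (exact photon budgets, IRF convolution,
  periodic fold-in), blinking-fluorophore movies (Bernoulli switching,
  pixel-integrated Gaussian PSF, Poisson + read noise), aggregate emitter
  geometries, and sigmoidal lifetime time courses — all seeded and
  bit-reproducible.

## Worked example

```r
library(flimstorm)

# a two-region TCSPC image: monomer-like 3.7 ns vs fibril-like 3.3 ns
irf  <- simulate_irf(fwhm = 0.2, n_channels = 256, window = 25)
tau  <- matrix(3.7, 6, 8); tau[, 5:8] <- 3.3
cube <- simulate_tcspc_image(decay_truth_map(tau, 4200, 0.95), irf, seed = 1)
map  <- fit_lifetime_map(cube, irf, mask = matrix(TRUE, 6, 8))
region_mean_lifetime(map, col(tau) <= 4)
#> Mean lifetime 3.683 +/- 0.000 ns (SEM, n = 1 images)
region_mean_lifetime(map, col(tau) > 4)
#> Mean lifetime 3.327 +/- 0.000 ns (SEM, n = 1 images)
```

The two region means recover the simulated ground truth to within the
estimator's sampling error (~0.02 ns SEM per region here), and their
separation (~0.36 ns) reproduces the monomer/fibril lifetime contrast.

The full pipeline — simulation, FLIM fitting, localization, morphometry,
kinetics, statistics — runs from one configuration:

```r
manifest <- run_pipeline(demo_config(seed = 7))
#> [flimstorm] flim: binning 0, region means 3.709 / 3.312 ns
#> [flimstorm] storm: 'ab40_24h' 1349 localizations
#> [flimstorm] storm: 'ab42_24h' 1368 localizations
#> [flimstorm] kinetics: lags 2.66 / 0.00 hr; endpoint p = 0.0901
round(manifest$stages$morph$mean_sizes, 1)
#> ab40_24h ab42_24h
#>    173.4    220.8      # nm; truth 160 (spheres) and 225 (rods)
```

Outputs (TIFF images, CSV tables, a JSON manifest with seed and per-file
MD5 checksums) land in the configured output directory. A thin command-line
wrapper is installed at `inst/scripts/flimstorm-pipeline.R`.

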