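---
title: "Methods: lifetime, localization and kinetics analysis of amyloid aggregation"
author: "flimstorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime, localization and kinetics analysis of amyloid aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimstorm)
```

# Scope and scientific background

When an environment-sensitive dye attached to the amyloid-beta peptide is
incorporated into beta-sheet amyloid, its fluorescence lifetime drops — from
about 3.7 ns for the monomeric conjugate towards 3.3 ns and below for
fibrillar material. That makes the per-pixel lifetime a label-specific,
intensity-independent reporter of aggregation state, usable in live cells.
This package implements the complete analysis around that idea:

1. **FLIM/TCSPC** — fit per-pixel photon-arrival histograms with an
   IRF-convolved monoexponential, after adaptive photon binning, and
   summarize lifetimes per region and over independent images;
2. **dSTORM** — localize stochastically blinking single molecules frame by
   frame, estimate each localization's precision with the Thompson closed
   form, and render localization-density histograms;
3. **morphometry** — segment aggregates in the rendered images, measure
   their longest dimension by pixel counting, and apply a resolution-limit
   filter before size summaries;
4. **kinetics and statistics** — fit sigmoids to lifetime-versus-time
   traces, extract lag times, and compare conditions with paired t tests or
   protected Fisher LSD.

Because no public raw data accompany the experiments this emulates, the
package ships seeded photon-level simulators for every input (module
functions prefixed `simulate_`). All tests, and the acceptance script, run
the analysis end-to-end on this synthetic data; the experimental values
(3.7/3.3 ns, a 2.5 hr lag, 160/225 nm aggregate sizes) enter only as
ground-truth *inputs* whose recovery is then checked.

# The TCSPC decay model

A TCSPC histogram records photon arrival times relative to the laser pulse
in `n` channels spanning one repetition period `T` (default `T = 25` ns for
a 40 MHz source, 256 channels — both configurable; the hardware class this
emulates does not fix the channel count). The fitted model is

$$F(t) = A \,\bigl(\mathrm{IRF} \circledast e^{-t/\tau}\bigr)(t) + B,$$

with `A` the decay photons, `B` a flat background per channel, and `tau` the
lifetime. Three numerical choices matter:

* **Exact channel-integrated kernel.** The discrete decay kernel is not the
  exponential sampled at channel centres but the analytic probability that a
  photon excited uniformly within one channel is *counted* `k` channels
  later, under the exponential folded periodically over `T`. Sampling at
  channel centres instead biases `tau` upward by tens of picoseconds at 128
  channels — larger than the estimator's own SD at typical photon counts —
  so the closed-form kernel is used everywhere, and is verified in the test
  suite against direct numerical double integration.
* **Periodic fold-in, no pile-up.** Photons emitted later than `T` wrap into
  the next excitation window (circular convolution). Re-excitation pile-up
  is not modelled: the count-rate regime this emulates stays below 1% of
  the repetition rate, where pile-up is negligible.
* **Poisson MLE with a profiled background.** The default fitter maximizes
  the Poisson likelihood — correct at TCSPC count levels — via a profile
  search over `tau`: at the Poisson MLE the fitted total equals the observed
  total, so the `(tau, A, B)` optimum reduces to a 1-D profile over `tau`
  with the background fraction optimized analytically constrained at each
  point (coarse log-spaced scan, then golden-section refinement;
  ties in the coarse scan break towards the smaller `tau`; `tau` is bounded
  to 0.1–10 ns). A Neyman-weighted least-squares fitter (`method = "lsq"`,
  weights `1/max(y, 1)`) is retained for parity with commercial TCSPC
  software; for fixed `tau` it solves `(A, B)` in closed form. A flat
  background is always floated: uniform dark counts exist in all TCSPC data
  and omitting `B` biases `tau`.

Binning follows the convention of commercial TCSPC software: a sliding
(2b+1)×(2b+1) window sum that preserves image dimensions, with the factor
`b` chosen globally per image as the smallest value bringing the *median*
masked pixel to at least 3500 photons (target window 3500–5000). Region
summaries use two-level averaging — per-image mean over converged pixels,
then mean ± SEM across images with equal image weights — matching how mean
lifetimes per time point are reported in FLIM studies. Masks can be supplied
or derived by Otsu thresholding of the photon-sum image.

# dSTORM localization

Frames are processed independently. Candidates are strict 8-neighbour local
maxima above `median + k · 1.4826 · MAD` of the frame (robust to the bright
spots themselves; `k = 6` by default — no threshold value is fixed by the
experiments emulated), with a 5-pixel duplicate-suppression radius. Each
candidate is fit with a 2-D Gaussian plus constant background.

Two estimator choices are deliberate:

* **Poisson-weighted least squares.** The spot fit minimizes the Poisson
  chi-square `sum((y - m)^2 / m)` rather than the unweighted residual sum.
  Unweighted Gaussian localization carries a known ~(4/3)^2 excess variance
  over the information bound; the Thompson precision formula
  $$\sigma_{loc}^2 = \frac{s^2}{N} + \frac{a^2}{12N} + \frac{8\pi s^4 b^2}{a^2 N^2}$$
  describes the bound-attaining estimator, and the package's Monte-Carlo
  tests require the empirical RMSE to sit within 20% of it.
* **Fit window from the camera.** The default window is the smallest odd
  integer covering ±3 PSF sigma (≥ 7 pixels; 11 at the default
  150 nm PSF sigma on 100 nm pixels). A fixed 7×7 window truncates ~10% of
  the photons at these PSF widths and measurably inflates the localization
  error at low photon counts.

Fits are *rejected* — a typed outcome, never an error — when the candidate
touches the border, the fitted width leaves `[0.5, 2] × s_expected`, the
integrated photons `N = 2 pi I0 s^2` fall below 100, or the optimizer fails.
Each accepted localization's precision is evaluated with the Thompson form,
taking `b` as the Poisson-plus-read-noise SD implied by the fitted
background level. No drift correction and no consecutive-frame linking are
performed (deliberate non-goals; hooks exist in the configuration).

Rendering assigns each localization to a half-open cell of a sub-pixel grid
(localization-density histogram). The image resolution is reported as the
worse of the precision-limited FWHM `2.355 · mean(precision)` and the
Nyquist sampling limit `2 / sqrt(density over the occupied support)`. This
surrogate replaces density-based blind resolution estimation, which is not
reproducible from its published description; it is a pluggable choice, and
Fourier ring correlation is the natural alternative.

# Morphometry

Aggregates are 8-connected components of rendered pixels holding at least 2
localizations (suppressing single-blink noise; no threshold is fixed by the
emulated experiments). The size measure is the one used for intracellular
aggregates: pixel counting along the longest dimension, implemented as the
maximum pairwise distance between member pixel centres — the Feret diameter,
correct for arbitrary orientations where a bounding-box diagonal is not —
plus one grid bin as an end-cap correction (so a single pixel measures one
bin and a collinear run of `n` pixels measures `n` bins). The orthogonal
extent (perpendicular to the Feret axis) gives an aspect ratio that
separates elongated from spherical species. Only aggregates whose longest
dimension exceeds the resolution limit are kept for size summaries
(mean ± SEM, pooled per condition across images).

The rendering bin defaults to 10 nm in the demonstration pipeline, roughly
2–3× the localization precision under the simulated photon budgets: much
coarser bins add pixel-quantization to the Feret extremes and, together with
the end-cap, bias sizes upward; much finer bins fragment the support at
realistic localization densities.

# Synthetic data: what it emulates and what it does not

* **TCSPC cubes** — exact per-pixel photon budgets (multinomial channel
  counts), IRF-convolved folded exponentials, uniform background. Not
  modelled: pile-up, after-pulsing, detector IRF drift.
* **Blinking movies** — per-frame Bernoulli on/off switching (memoryless; no
  explicit dark-state kinetics or photobleaching), Poisson photons through a
  pixel-integrated Gaussian PSF, Poisson background, Gaussian read noise
  (an adequate EMCCD approximation at these photon levels; the full gain
  register cascade is not modelled). Defaults put the system in the sparse
  activation regime that defines dSTORM (~0.5 emitters on per aggregate per
  frame).
* **Aggregate geometries** — uniformly labelled discs ("sphere", the 2-D
  projection) and 3:1 rectangles ("rod"). `size` always denotes the longest
  dimension; the rod rectangle is scaled so its diagonal equals `size`,
  keeping the generator's size parameter commensurate with the pixel-counting
  measurement made downstream.
* **Kinetic traces** — a four-parameter logistic
  `L(t) = Linf + (L0 - Linf) / (1 + exp(k (t - t50)))` plus Gaussian noise;
  optionally a per-replicate offset emulating image-to-image variability.

Passing tests on these data demonstrate estimator correctness and
calibration under the stated noise models; they do not certify behaviour
under cellular autofluorescence, drift, dense emitter overlap, or
multi-exponential decays (multi-exponential and phasor analysis are
non-goals).

# Kinetics and statistics

The lag phase of an aggregation time course is defined by the tangent
construction `lag = t50 - 2/k` — the intersection of the maximal-slope
tangent with the baseline, the standard convention in amyloid kinetics; the
published account this emulates never defines "lag phase" operationally, so
the definition is exposed and alternatives (e.g. time to 5% change) can be
substituted. Negative tangent intercepts are clamped to zero and read as
"no detectable lag", the behaviour of the fast-aggregating 42-residue
peptide. Sigmoid fits use Levenberg–Marquardt from a grid of `t50` and rate
starts; a start that exhausts its evaluation budget in the flat
parameter valley of lag-free traces (where the transition partly precedes
the observation window) still contributes its residual optimum rather than
being discarded. Mechanistic nucleation-elongation rate laws are out of
scope: interpreting rate profiles mechanistically would require
intracellular concentrations that these experiments do not measure.

The statistics mirror the experimental analysis: two-sided paired Student
t tests for single comparisons and Fisher's least significant difference for
multiple comparisons, using the pooled one-way-ANOVA error term. The LSD is
*protected* — pairwise significance is only declared when the omnibus F
rejects at the same alpha (whether the original analysis protected its LSD
is not stated; protection is the conservative choice, and it keeps the
per-comparison type-I error under the global null below alpha, which the
test suite verifies by simulation). Significance stars follow the
conventional 0.05/0.01/0.001/0.0001 thresholds. Both tests are implemented
as explicit arithmetic and are required by the test suite to match
`stats::t.test` and an `aov`-based reference to 1e-6; sidedness is two-sided
throughout.

# Problem sizes and determinism

The shipped tests and the acceptance script size their simulations to the
smallest problems that still constrain the estimators: 6×8-pixel two-region
TCSPC images at ~4200 photons/pixel, 200-seed lifetime calibrations,
400-frame single-emitter precision runs, 1200-frame aggregate movies with
250 fluorophores (about 500 localizations per aggregate), 20-seed kinetic
contrasts, and 10^4-replicate null calibrations. Every generator takes an
explicit seed and identical seeds give bit-identical outputs; the pipeline
manifest records seed, configuration hash and per-file MD5 checksums so a
run can be verified byte for byte.

# Worked example

```{r example, eval = FALSE}
irf <- simulate_irf(fwhm = 0.2, n_channels = 256, window = 25)
tau <- matrix(3.7, 6, 8); tau[, 5:8] <- 3.3
cube <- simulate_tcspc_image(decay_truth_map(tau, 4200, 0.95), irf, seed = 1)
map <- fit_lifetime_map(cube, irf, mask = matrix(TRUE, 6, 8))
region_mean_lifetime(map, col(tau) <= 4)   # monomer-like region
region_mean_lifetime(map, col(tau) > 4)    # fibril-like region

manifest <- run_pipeline(demo_config(seed = 1))
```

# Known limitations

* Single-exponential decays only; mixtures within a pixel report an
  effective lifetime.
* No drift correction, frame linking, 3-D/astigmatic localization, or
  multi-emitter fitting; dense-overlap frames lose localizations.
* The resolution estimate is a documented surrogate, not the published
  blind density-estimation method.
* Lag times from the tangent construction depend on the fitted rate; for
  transitions faster than the sampling interval the lag uncertainty is
  dominated by `t50`.
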