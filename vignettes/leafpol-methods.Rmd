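---
title: "Leaf surface phenotyping from focus stacks and polarized reflectance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf surface phenotyping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafpol)
```

## The problem

Leaf surfaces express a handful of recurring phenotypes — glossy epicuticular
wax that fills the grooves between epidermal cells into a smooth film,
glaucous wax that forms a scattering bloom, dense trichome (hair) cover, and
glabrous surfaces with neither — and these phenotypes change how the leaf
reflects light.  Specular reflection happens at the air–cuticle interface
before the light meets any pigment, and at Brewster's-angle geometry
(`atan(n)` ≈ 55° from nadir for a cuticle refractive index of 1.45) it is
strongly partially polarized.  Diffuse reflection, re-emitted after
scattering inside the leaf, is unpolarized and carries the pigment
signature.  Rotating a linear polarizer between the sample and the sensor
therefore separates the two components, and the separation carries phenotype
information that is measurable without touching the leaf.

`leafpol` implements the full analysis chain:

1. **Shape-from-focus reconstruction** of microscope focus stacks into an
   in-focus composite and a metric depth map.
2. **Cell-scale morphology metrics** from hand-traced cell polygons: cell
   size, margin undulation, and cell cap aspect ratio.
3. **Spectral feature extraction** from 19-orientation polarized reflectance
   sweeps: the polarized bidirectional reflectance factor average
   \(R_{Qav}\) and the red-edge diffuse ratio \(DIFF_R\).
4. **Four-class quadratic discriminant classification** with equal priors
   and a Monte-Carlo random-split evaluation harness.
5. **Synthetic generators** for every input, with retained ground truth.

## Shape-from-focus reconstruction

A focus stack is an ordered image series of one field taken at stage heights
spaced 0.005 mm (100×) or 0.001 mm (500×); depending on surface topography
a stack holds roughly 10–50 slices.  Per pixel, the slice with the highest
gradient magnitude is declared in focus; the composite takes that slice's
intensity and the depth map its stage height.

* **Sharpness operator.**  The L2 magnitude of central intensity
  differences (one-sided at borders).  The selection is driven by the
  sharpness *contrast* across slices, not by the particular operator, so the
  simplest operator consistent with "the gradient of each pixel" is used.
* **Tie-breaking.**  Equal sharpness selects the lowest slice index, for
  determinism.
* **Post-filters.**  A 10×10 median filter followed by a 15×15 Gaussian
  filter (σ = 15/6 = 2.5 px, the usual kernel-width convention).  Both are
  applied to the depth map by default — their purpose is to suppress
  selection noise and capture the shape of a single cell — and optionally to
  the composite behind `filter_composite`; which target the original
  protocol filtered is ambiguous, so both behaviors are provided.
* **Even kernel origin.**  A 10×10 window has no center pixel.  The origin
  sits at position (5, 5) of the window (offsets −4…+5, extending one pixel
  further down/right), with nearest-edge padding.  A consequence worth
  knowing: an even kernel translates gradients by about half a pixel per
  pass, so the median filter is only idempotent *at the resolution of the
  depth map* — a second pass never moves a pixel by more than one stage
  step, which is what the test suite asserts.
* **Calibration.**  The default pixel scale is 9.8×10⁻⁵ mm/pixel (500×);
  the 100× scale must be supplied by the user.  `reconstruct_3d()` maps
  pixel (row, col) to (y, x) = (row, col) · pixel scale and drapes the
  composite over the depth map.

## Morphology metrics

All metrics operate on a hand-traced, simple (non-self-intersecting) cell
polygon; five tracings per sample are averaged by `summarize_sample()`, and
cells whose cap ratio is undefined (flat depth) are excluded from that
metric's average rather than mapped to infinity — mirroring the exclusion of
unmeasurable samples.

* **Cell size**: polygon area × (pixel scale · 1000)² µm².  The continuous
  shoelace area is the default (resolution-independent); a rasterized
  pixel-count mode reproduces a counting workflow, and the two agree within
  2 % at realistic cell sizes.
* **Margin undulation**: traced area over convex-hull area (hull via
  `chull()`), in (0, 1]; exactly 1 for a convex ("completely round") cell.
  Invariant under rotation, translation, and uniform scaling.
* **Cell cap aspect ratio**: the highest and lowest depth-map points inside
  the trace are the peak and valley; the ratio is
  \(2c\sqrt{(x_p-x_v)^2+(y_p-y_v)^2} / (z_p-z_v)\) with \(c\) the pixel
  scale in mm/px.  The factor 2 — treating the peak-to-valley run as half a
  cell width — is implemented verbatim as defined, even though it is an
  unusual convention.
* **Pubescence coverage**: percent of mask pixels traced as hair.  For
  dense, uniform trichomes (above roughly 25 % cover) `coverage_by_count()`
  approximates coverage as hair count × mean area of 5 sampled hairs /
  field area; the 25 % switch is advice, not enforced.

## Spectral features

Each sample contributes 19 reflectance-factor spectra (400–1700 nm) at
polarizer orientations 0°–90° in 5° steps.  Processing:

1. **Preprocess**: subtract the dark reference and divide by the polarizer
   transmittance (measured with source and sensor aligned).  The
   transmittance is floored at 10⁻⁶; a transmittance at or below the floor
   inside the feature window is an error rather than a blow-up.
2. **Extrema selection**: because the leaf is never perfectly flat and
   aligned, the minimum is not always at the nominal parallel orientation.
   The default selects whole scans by their mean over 500–900 nm, which
   preserves spectral shape for the diffuse ratio; whether the original
   selection statistic was a windowed mean, a full-spectrum comparison or a
   visual choice is unstated, so the windowed mean is this package's
   documented choice, with a per-wavelength envelope mode behind a flag.
   Ties break toward 0° (minimum) and 90° (maximum).
3. **Polarized BRF**: \(R_Q = (R_{max}-R_{min})/2\), and the total
   \(R = (R_{max}+R_{min})/2 = R_Q + R_{min}\) — an identity the test suite
   asserts pointwise on every synthetic scan set.
4. **Features**: \(R_{Qav}\) is the unweighted mean of \(R_Q\) over grid
   points in [500, 900] nm inclusive; \(DIFF_R = R_{min}(765)/R_{min}(680)\)
   (numerator at 765 nm — NIR over red gives ratios above 1 for green
   leaves), linearly interpolated when off-grid, never extrapolated.

Thin-film interference on the polarizer superimposes a ripple on the
specular component that cannot be removed by reference correction; the
mitigation is exactly the 500–900 nm averaging, which cancels a zero-mean
ripple over whole periods (asserted to 10⁻⁶ relative).  The whole-scan
selection guarantees a nonnegative *window average* of \(R_Q\); pointwise
nonnegativity holds in the per-wavelength envelope mode.

## Classification and evaluation

Each phenotype class is modeled as a bivariate Gaussian over
\((R_{Qav}, DIFF_R)\): sample means, unbiased (n−1) covariances, and a
ridge of 10⁻⁸·trace/2 only when a covariance's condition number exceeds
10¹².  Priors are equal (1/4) regardless of class frequency, so predictions
are invariant to duplicating a class.  Features are used on their native
scales (QDA is scale-equivariant through its covariances).  Ties break
toward the earlier label in the fixed order glossy < glaucous < hairy <
glabrous.

The Monte-Carlo harness repeats: draw a uniform random train/test partition
(redrawn if a class is absent from training; a training class with fewer
than 3 samples fails that run's fit, and runs failing this way are skipped —
more than 1 % skips aborts the evaluation), fit on the training set,
classify the test set, and record overall and per-class rates and the
confusion matrix.  A master seed spawns per-run sub-seeds so any single run
is independently reproducible.  Two limits anchor the implementation to
independent oracles: forcing a pooled covariance must reproduce linear
discriminant analysis exactly, and identity covariances must reproduce the
nearest-class-mean rule.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of (spec, seed) and returns its ground
truth alongside the data.

* **Surfaces** (`generate_surface()`): a square lattice of cosine cell
  domes (default pitch 25 µm, amplitude 3 µm) whose boundary radius is
  modulated by a per-cell random lobe pattern scaled by `margin_waviness`
  (0 gives circular, convex cells); optional trichome stamps (erect disks
  or lying ridges) until a target areal density is reached; glossy wax
  raises the groove floor to 55 % of the dome height (strictly reducing
  height variance), glaucous wax speckles the texture.  Cell boundary
  polygons are returned for trace-metric tests.
* **Focus stacks** (`generate_focus_stack()`): slice *i* blurs the texture
  per pixel with a Gaussian of σ = blur coefficient × |stage height −
  surface height|; the σ field is quantized to at most 96 levels spaced at
  most half the per-step σ increment, so adjacent slices never collapse
  onto one blur level.  Gaussian defocus is a desk-scale surrogate — the
  real microscope kernel is unknown and unneeded, since only the sharpness
  *ordering* across slices matters.
* **Scan sets** (`generate_polarized_scanset()`): R(θ, λ) = D(λ) +
  S(λ)·sin²(θ − tilt) + noise.  D is a parametric green-leaf curve (green
  Gaussian bump + logistic red edge to a NIR plateau), deliberately not a
  radiative-transfer model: only the 500–900 nm shape and the 680/765
  contrast matter downstream.  The sin² modulation follows specular light
  polarized perpendicular to the incidence plane at Brewster geometry; the
  tilt offset moves the minimum off 0°.  The interference ripple multiplies
  the specular term only, so the retained ground truth satisfies
  \(R_Q = S/2\) and \(R_{min} = D\) exactly at zero tilt and noise.
* **Feature clouds** (`generate_feature_dataset()`): per-class bivariate
  Gaussians truncated to the published phenotype ranges — glabrous
  \(R_{Qav}\) within [0.48, 4.32]×10⁻⁴, all classes within
  [0.30, 19.63]×10⁻⁴, no non-glossy sample above 8×10⁻⁴, hairy
  predominantly below 2×10⁻⁴.  The class means and covariances are
  calibrated to those ranges and to a handful of published exemplar values,
  not to any measured dataset, and the per-class \(DIFF_R\) distributions
  in particular are approximate: glaucous bloom and dense trichomes raise
  visible diffuse reflectance, so those classes get lower \(DIFF_R\) than
  glossy/glabrous green leaves.

What the synthetic data does **not** emulate: wax microstructure
(platelets, rodlets), wavelength-dependent refractive index, registration
error between slices, pigment variation beyond the red edge, detector
nonlinearity.  Passing tests therefore demonstrate the correctness of the
algorithms under the stated generative model, not field performance on real
leaves.

## Numerical choices and problem sizes

* RNG state is saved and restored around every generator; seeds below 2³¹.
* Degenerate inputs are classed errors (`leafpol_parameter_error`,
  `leafpol_geometry_error`, `leafpol_flat_cell_error`, …), never silent
  NaNs.
* The test suite exercises reconstruction on 48–96 px fields with 10–30
  slices, classifier properties on 50×50 prediction grids, parameter
  recovery at 10⁴ samples per class, and Monte-Carlo stability at 500–2000
  runs on a 349-row table split 150/199 — sizes chosen so the whole suite
  runs in well under a minute while estimates stay comfortably inside their
  tolerances.  The harness itself runs 10,000-replicate evaluations in tens
  of seconds when asked.

## Known limitations

* No slice registration: stacks are assumed acquired in a fixed holder.
* The exclusively-glossy high-\(R_{Qav}\) region is enforced by truncation
  in the generator; the classifier itself fits on all data.
* Low-chlorophyll (pink/yellow/white) leaves need a different diffuse-ratio
  band and are out of scope.
* Wax and trichome *loading* are classified, not quantified.
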