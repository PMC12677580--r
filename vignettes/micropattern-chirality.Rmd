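---
title: "Quantifying cell chirality on rectangular micropatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell chirality on rectangular micropatterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralcell)
```

## The measurement

Confluent cells confined on a rectangular adhesive island align their actin
cytoskeleton close to the rectangle's long axis, but with a small,
cell-type-specific angular bias. Viewed from the culture-medium side, a
left-up to right-down bias (dominant angle $\theta < 0$) is called
clockwise (CW) chirality; left-down to right-up ($\theta > 0$) is
counterclockwise (CCW). The measurement unit is one rectangle: the texture
of a phalloidin (F-actin) image of its central region is reduced to a
single dominant orientation $\theta \in (-90°, 90°]$, and chirality is a
property of the *population* of per-rectangle angles — the sign of their
axial circular mean, when a one-sample test excludes zero.

`chiralcell` implements the full chain:

1. **Grid registration.** The stitched image is anchored on an "F"
   fiducial at the tape center. The glyph is intrinsically chiral, so an
   accidentally mirrored export — which would silently invert every
   chirality call — is detected by comparing the glyph with its mirror
   image and aborts the run.
2. **Primary cropping.** Each rectangle is cut out with half-gap margins
   (900 × 600 µm for the default 600 × 300 µm rectangles with 300 µm
   gaps). Vertically oriented rectangles are rotated 90° clockwise so the
   long axis is always horizontal; the rotation subtracts 90° (mod 180°)
   from displayed texture angles, which is exactly compensated, so pooling
   both orientations adds no angular bias (and cancels illumination
   artifacts that would affect the two orientations differently).
3. **Coverage filter.** The cell-attached area is segmented by Otsu's
   threshold on a low-passed copy of the crop (Gaussian σ = 15 µm, so
   stripe-scale intensity minima do not fragment the mask), holes smaller
   than (20 µm)² are filled, and rectangles whose attached area is less
   than 80% of the nominal 600 × 300 µm pattern are excluded. The centroid
   of the mask defines the cell center.
4. **Secondary cropping.** A 400 × 200 µm window centred on that centroid
   (clamped inside the primary crop) restricts the measurement to the
   central region, away from edge-aligned border cells.
5. **Dominant orientation.** The structure tensor — the region-averaged
   outer product of Gaussian-derivative intensity gradients,
   $J_{xx} = \langle f_x^2\rangle$, $J_{xy} = \langle f_x f_y\rangle$,
   $J_{yy} = \langle f_y^2\rangle$ — gives the dominant texture direction
   $\theta = -(\tfrac12\operatorname{atan2}(2J_{xy},\,J_{xx}-J_{yy}) + 90°)$
   (the outer negation converts image coordinates, row axis pointing down,
   to the display convention) and the coherence
   $\sqrt{(J_{xx}-J_{yy})^2 + 4J_{xy}^2}/(J_{xx}+J_{yy}) \in [0, 1]$.
6. **Axial circular statistics and the chirality call** (below).

## Axial statistics on the doubled circle

Orientation angles are axial: $\theta$ and $\theta + 180°$ are the same
fiber. All statistics therefore double the angles onto the full circle,
analyse them there, and halve the results:

* circular mean $= \tfrac12 \operatorname{atan2}(\sum\sin 2\theta_i,
  \sum\cos 2\theta_i)$;
* mean resultant length $\bar R$ of the doubled angles; circular SD
  $= \tfrac12 \sqrt{-2\ln\bar R}$ (in degrees after conversion), halved
  symmetrically with the mean so that printed SDs live on the half-circle
  scale;
* the 95% CI of the mean direction uses the large-sample circular
  dispersion $\hat\delta = (1-\hat\rho_2)/(2\bar R^2)$ with half-width
  $\arcsin(z_{0.975}\sqrt{\hat\delta/n})$ on the doubled circle
  ($\hat\rho_2$ = resultant length of the twice-doubled angles); when the
  arcsine argument reaches 1 or $n < 25$ a seeded percentile bootstrap
  (9999 resamples) replaces it;
* the one-sample mean-angle test rejects $\mu_0$ iff $\mu_0$ lies outside
  that CI (taken axially); the chirality call is CW when $\mu_0 = 0$ is
  rejected with a negative mean, CCW with a positive mean, indeterminate
  otherwise;
* two groups are compared with Watson's $U^2$ on the doubled angles,
  $U^2 = \frac{nm}{N^2}\bigl[\sum_k d_k^2 - (\sum_k d_k)^2/N\bigr]$ with
  $d_k$ the difference of empirical CDFs at the pooled order statistics
  (ties block-averaged). The p-value comes from random label permutations
  (default 9999, seeded — correct level at any sample size); the classical
  asymptotic series is available as `method = "asymptotic"`. No
  multiple-testing correction is applied: comparisons are reported as
  single pairwise tests, and users testing many pairs should adjust
  externally.

The histogram "peakedness" statistic is the ordinary linear excess
kurtosis of the angle values. Note it is *not* monotone in alignment
strength over the whole range: it rises with concentration while spread is
large (axial SD ≳ 25°), peaks near $\kappa \approx 2$, and returns to 0
(the narrow-Gaussian limit) for tight alignment, so it is only a useful
spread companion in weakly aligned populations.

## The synthetic scene generator

Every stage is testable without microscopy data through
`generate_scene()`, which emulates the reference tape: 453 rectangles of
600 × 300 µm, 300 µm gaps, inside a 19 mm circle, with the "F" glyph at
the center. The exact CAD placement of the published tape is not public;
the generator packs rows of cells (rectangle + half-gap margins)
alternating horizontal and vertical orientation, keeps cells wholly inside
the circle, and retains the `n_rectangles` closest to the center — this
reproduces the published count and spacing, not the literal arrangement.
At the default 2 µm/px the full canvas is 9500 × 9500 px.

Per-rectangle truth angles are drawn from an axial von Mises law: doubled
angles $\sim \mathrm{vM}(2\mu, \kappa)$, halved back. The defaults
($\mu = -8°$, $\kappa = 6$) represent a clearly CW-aligned population of
the kind the assay is designed to detect; published assays span roughly
$\kappa \approx 0.6$–$4$ (axial SD 16–46°), so the default is a
moderately concentrated case. The texture is an oriented sinusoid
(wavelength 20 µm, the scale of aligned actin-bundle spacing) on a dim
uniform base emulating diffuse cytoplasmic signal — chosen because the
structure tensor's response to a plane wave has a closed-form dominant
direction, making recovery exactly checkable — plus additive Gaussian
noise. Cell coverage is modelled as a centred, equal-aspect sub-rectangle
holding `sqrt(coverage)`-scaled sides; the default coverage mixture (80%
of rectangles uniform on 0.88–1, 20% on 0.40–0.70) straddles the 80%
filter while avoiding its immediate neighbourhood, so the expected
inclusion decision is unambiguous. The image scale is configurable
because the published pixel size for the micropattern images is not
stated.

What the generator does **not** emulate: single-cell shapes, nuclei or
multi-channel content, intensity vignetting and stitching seams, edge
cells crawling over pattern borders, or spatially correlated noise.
Passing the end-to-end tests therefore demonstrates correctness of the
geometry, bookkeeping and statistics, and accuracy of the estimator on
band-limited oriented texture — not robustness to every real-microscopy
artifact.

## Numerical choices and degenerate inputs

* Gradients use derivative-of-Gaussian kernels, σ = 1 px by default,
  normalised exactly against a unit ramp; a 3σ border where the
  convolution is incomplete is excluded from tensor averages.
* Regions with tensor energy below $10^{-12}(\mathrm{var}(I) + 1)$ (blank
  crops) are flagged indeterminate and excluded downstream rather than
  raising an error; an all-background crop yields area fraction 0 and is
  excluded by the coverage rule.
* The segmentation requires a foreground–background mean contrast of at
  least 0.1 (on the [0, 1] scale) so that Otsu's split of pure background
  noise is not mistaken for cells.
* $\theta = -90°$ ties are mapped to $+90°$ (half-open axial interval);
  a perfectly balanced axial set (e.g. exactly $\{-45°, +45°\}$) has no
  mean direction and raises an explicit error.
* Secondary windows are clamped at crop borders rather than padded — no
  intensity is ever fabricated.
* Permutation p-values use the add-one estimator $(1 + \#\{U^2_{perm}
  \ge U^2\})/(B + 1)$; with $B$ permutations the smallest attainable
  p-value is $1/(B+1)$.

## Design decisions that were genuinely open

* The segmentation method behind "fluorescence intensity relative to
  background" is not published; Otsu's threshold was chosen as the
  parameter-free standard for bimodal stain/background histograms, and
  the area denominator is the nominal 600 × 300 µm pattern (the stated
  reference for the 80% rule), not the 900 × 600 µm crop.
* The "center of the cell-attached area" is computed as the mask
  centroid (not the bounding-box center).
* The one-sample procedure is CI inversion with Fisher's
  circular-dispersion interval — the decision rule as published is
  literally "μ0 outside the 95% CI", and this is the large-sample CI
  both common circular-statistics stacks implement.
* Published p-values for $U^2$ are not bit-reproducible targets (the
  exact test variant used upstream is unstated); the statistic and the
  reject/not-reject decision are the stable quantities.
* Printed kurtosis values are treated as linear excess kurtosis of the
  half-circle angles.

## Problem sizes used in validation

The shipped validation suite uses: stripe fixtures of 128–256 px;
parameter recovery at $n = 10^4$ draws; CI coverage over 5000 simulated
samples ($n = 300$, $\kappa = 6$); Watson $U^2$ null calibration over
2000 replicates (499 permutations each, $n = m = 50$); and one full-scale
synthetic tape (453 rectangles, 9500² px) for end-to-end recovery. These
sizes make Monte-Carlo error small against the asserted tolerances while
keeping a full run in a few minutes on one core.

## A compact example

```{r example, eval = FALSE}
library(chiralcell)

# a small synthetic tape with a CW-aligned population
grid <- grid_spec(n_rectangles = 60, layout_diameter = 8200)
scene <- generate_scene(grid, scene_params(mu_deg = -8, kappa = 6, seed = 11))
res <- run_image_pipeline(scene)
res$summary
autoplot(res)

# statistics straight from an angle table
tab <- read_angle_table(system.file("extdata", "synthetic_angles.csv",
                                    package = "chiralcell"))
run_stats_only(tab, n_perm = 999, seed = 1)
```

## Known limitations

* The estimator reports a single dominant direction per region; strongly
  bimodal textures (crossing fiber families) are summarised by whichever
  direction dominates the averaged tensor, with low coherence as the only
  warning sign.
* Grid registration assumes the stitched image is already rotationally
  aligned to the tape (the fiducial anchors translation and detects
  mirroring, not rotation).
* Dish-level clustering is not modelled: angles from one tape are treated
  as independent, as in the published analysis; replicate-level inference
  should aggregate per dish.
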