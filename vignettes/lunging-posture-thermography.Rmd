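---
title: "Quantifying the postural and thermal response of horses to lunging"
author: "equilunge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the postural and thermal response of horses to lunging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equilunge)
```

## The problem

Lunging — exercising a horse on a long line around a circle — is routinely
performed either with a freely moving head (FMH) or with a lunging aid that
constrains the head/neck angle (HNA): a chambon (CH, elastic, opens the
HNA toward 110–115°), a rubber band (RB, elastic, closes it toward
85–90°), or triangle side reins (TRs, stiff, closing). Whether a given aid
actually changes the horse's working posture, and whether that change is
accompanied by increased metabolic heat output, are questions a trainer
cannot answer by eye. `equilunge` implements two non-contact measurement
pipelines to answer them from ordinary photographs and infrared
thermograms of a 13-horse, 4-condition, before/after study design.

## The posture model

Posture is encoded as a 30-point semilandmark curve along the dorsal
profile, from the base of the tail to the end of the facial crest. Eight
anatomical anchors are digitized (tail base, lumbosacral joint, L1, T10,
atlantooccipital joint, temporomandibular joint, medial eye canthus,
facial crest end) and fixed runs of 3, 2, 6 and 11 intermediate
semilandmarks are interpolated between the first five anchors, giving the
canonical index map `1, 5, 8, 15, 27, 28, 29, 30` for the anchors and the
region partition hindquarter (1–8), back (9–19), head/neck (20–30). In field
practice the intermediates are digitized by hand; since manual digitization
is not reproducible in software, `build_curve_landmarks()` places each run
at equal arc length along a chord-length-parameterized natural cubic
spline through the anchor polyline — a smooth, deterministic surrogate
that is equivariant under rigid motion of the anchors and pins the anchors
bit-exactly. The digitization convention leaves the positions of the three head
anchors within the 30-point ordering underdetermined (the insertion list
covers only the first five anchors); the index map above is the one
consistent reading that
reproduces the stated insert counts and region grouping, and it puts the
eye canthus at index 29 and the facial crest end at index 30.

Configurations are compared in shape space. Generalized Procrustes
Analysis (`gpa()`) centers every configuration, scales it to unit centroid
size (`centroid_size()` = root summed squared distances of landmarks to
their centroid), and iteratively rotates each one (proper rotations only)
onto the evolving consensus until the consensus moves less than `tol`
(default `1e-8`, maximum 100 iterations, the conventional values). Because 2-D configurations are complex
vectors, the optimal rotation has the closed form
$e^{i\theta} = \langle w,\bar z\rangle / |\langle w,\bar z\rangle|$, which
is what the implementation uses; the whole fit for 104 configurations
takes milliseconds, which is what makes the calibration suites below
affordable.

### PCA, tangent projection, and a deliberate trade-off

Shape variation is summarized by PCA of the covariance matrix of the
superimposed coordinates (`pca()`) — the covariance (not correlation)
convention standard in morphometric software. Unit-size Procrustes coordinates live
on a curved manifold, so the raw coordinate covariance has small spurious
eigenvalues beyond the shape dimension $2k-4 = 56$, and a rank-56
reconstruction misses the curvature component. The two standard contracts
— "aligned configurations have centroid size exactly 1" and "at most 56
nonzero eigenvalues, reconstruction exact" — cannot both hold on one
matrix. `equilunge` keeps both, in the places where each is standard:
`gpa()` returns unprojected coordinates (unit size exact), and `pca()`
orthogonally projects the deviations into the tangent space at the
consensus before the eigendecomposition, exposing the projected matrix as
`tangent_coords`. Reconstruction (`center + scores %*% t(vectors)`) is
exact against `tangent_coords` to machine precision. PC signs are fixed
(largest-magnitude loading positive) so reports are deterministic.

`eigenvalue_variance_stats()` reports the dispersion of the spectrum under
three conventions (raw population variance over the reported eigenvalues;
the same scaled by squared total variance; and additionally rescaled by
$p^2/(p-1)$ for $p$ variables). Several conventions for these indices circulate in morphometric
software; the implementations here are explicit, documented choices.

### Procrustes ANOVA

Classifier effects on shape are tested with a Goodall-style decomposition
(`procrustes_anova_shape()`): between-group and within-group sums of
squared Procrustes deviations, with degrees of freedom multiplied by the
shape dimension — $(g-1)\cdot 56$ and $(n-g)\cdot 56$ for 30 2-D
landmarks, giving the design constants 168 (4 conditions) and 56 (2 time
points) regardless of the data. The p-value is parametric (F
distribution) by default, with a label-permutation option (10,000
rounds, seeded) as the distribution-free alternative — on Gaussian synthetic data the two agree within 0.02. Centroid
size is tested with an ordinary one-way ANOVA (`anova_centroid_size()`,
delegated to `stats::lm`). Goodall's F assumes isotropic, equal
landmark-wise variation; the simulation suite below verifies that under
that assumption its size is close to nominal (empirically ≈ 0.054 at
α = 0.05 with n = 104), and the test is known to be approximate when the
assumption fails.

Grouped PC scores are displayed with 0.9-probability confidence ellipses
(`confidence_ellipse()`): mean and covariance of the group's 2-D scores
with squared Mahalanobis radius $\chi^2_2(0.9) \approx 4.605$, i.e.
isotropic unit-variance scores give semi-axes $\approx 2.146$.

## The Pixel-Counting Protocol

Thermograms are rendered with a fixed 28.0–38.0 °C range; everything below
28 °C, and everything manually masked, is exact `#000000`. The body
surface is *all and only* non-`#000000` pixels — a deliberate exact-match
rule (a near-black `#010101` pixel is surface), because the masking step
of the protocol guarantees true background is exactly black. Surface
colors are grouped into five 2 °C bins — [28,30), [30,32), [32,34),
[34,36), [36,38] — half-open below, closed at the top, matching the range
set-up that clips at 38 °C; temperatures above 38 clamp into the top bin.

Classification is by color, not by stored temperatures, emulating the
analysis of exported pseudocolor images: each distinct surface color
(exact histogram, `extract_color_histogram()`) is converted to CIELAB
(`srgb_to_lab()`, sRGB/D65, 2.4-exponent transfer, 8-bit round-half-up
quantization) and assigned to the bin whose reference color — the palette
at the bin's temperature midpoint — minimizes the CIE76 distance
$\Delta E^* = \sqrt{\Delta L^{*2} + \Delta a^{*2} + \Delta b^{*2}}$
(`delta_e76()`), ties toward the cooler bin. Per-bin counts over the
total surface give `surface_profile()`.

The proprietary camera palette is unavailable, so the package bundles a
synthetic one (`default_palette()`): within each bin the color ramps
linearly in sRGB inside that bin's family (dark purple→navy, blue,
green, yellow→orange, red), with a hard family change at each bin edge.
A continuous ramp was rejected on numerical grounds: colors rendered at
29.99 and 30.00 °C would be identical after 8-bit quantization, so no
nearest-reference rule could place the classification boundary exactly at
the bin edge. With hard edges the round trip
`classify(render(t)) == bin(t)` holds *exactly* for every `t` in a
0.01 °C sweep of the range, and profiles of rendered scenes equal the
direct per-pixel temperature tally pixel-exactly — both are tested.
Alternative palettes load from a CSV of per-bin stops (`read_palette()`).
Raster I/O is lossless PNG (plus raw CSV temperature grids); lossy
formats are unsupported because compression quantization can move colors
across bin boundaries.

Bin percentages are compared nonparametrically, justified by Shapiro–Wilk
checks on each series (`normality_check()`): Kruskal–Wallis
with tie-corrected H (`kruskal_wallis()`, delegated to
`stats::kruskal.test`) followed by Dunn's pairwise z tests with
tie-corrected variance, written here directly since no Dunn implementation
ships with the stack. The multiplicity correction within each comparison
family is Bonferroni by default, and the choice is recorded in the
output metadata. Pairwise
outcomes are summarized as lowercase compact-letter displays
(`compact_letters()`, exhaustive maximal-clique assignment, deterministic
order), and box plots show median, quartiles (linear-interpolation
convention) and min/max whiskers with no outlier trimming.

## What the synthetic generator emulates

No images from the study are public, so the generator is a first-class
module and defines the conditions under which everything is tested.

**Landmarks** (`generate_landmark_dataset()`): 13 horses × 4 conditions ×
2 time points = 104 configurations, individuals coded 1–52 (13 per
condition), ID codes `A001`–`D152`. Each horse is the fixed template
profile (`template_anchors()`, a versioned dorsal polyline framed for a
968 × 709 px raster with its HNA constructed exactly) under a per-horse
log-normal size factor (SD 0.04) and a small landmark-wise conformation
jitter (SD 0.5 px). Every observation adds isotropic digitization noise
(SD 5 px, a realistic scatter for ~900 px profiles). After-lunging
observations add the condition's vertical displacement field: peak ±2
noise-SD with a Gaussian taper (width 2 indices) — FMH raises the
atlantooccipital joint and tail base and lowers the mid-back; CH is
identically zero; RB raises the mid-back; TRs mirrors FMH. The source
reports significance, not effect sizes, so the 2-SD peak is a calibration
choice: it gives the Procrustes ANOVA ≈ 1.0 power in the RB subset at
n = 13/cell, i.e. "clearly detectable", while CH stays at its nominal
false-positive rate. The conformation jitter is deliberately small
relative to the noise: horses appear in both time groups, so shared
horse-level shape variance inflates the Goodall residual without
inflating the between-group term, and a large jitter would make the
zero-effect test conservative rather than nominal.

**Thermograms** (`generate_thermal_scene()`): a horse silhouette (trunk
ellipse, neck wedge, head, four legs) on black background, default
242 × 177 px (the native 968 × 709 raster downscaled 4× for speed; the
full size is a parameter). Target bin-fraction vectors — before lunging
(0.35, 0.35, 0.18, 0.12, 0) for all conditions, and per-condition after
vectors concentrating FMH in bins 3–4, CH in 3–4 with a bin-1 floor, RB
across 3–5, and TRs in 4–5 with the largest bin-5 share — are calibration
choices emulating the reported qualitative orderings (before-lunging
homogeneous with an empty top bin; after-lunging heterogeneous). Each
image jitters the target (SD 0.02, renormalized), apportions surface
pixels by largest remainder, lays bins out cool-to-warm along a smoothed
tail-to-head gradient (cool hindquarter, warm cranial back and upper
neck), and draws temperatures uniformly within each bin. The realized
fractions are returned as exact ground truth and the full
render→mask→classify→count pipeline reproduces them pixel-exactly.

What the generator does **not** emulate: photographic perspective and
digitization bias, anatomically realistic thermal textures (vessel
patterns, tack marks), anti-aliased silhouette edges (real manual masking
may leave blended pixels; the exact-#000000 rule is applied regardless), ambient-condition drift, and any correlation between a horse's
posture change and its thermal response. Green tests therefore establish
that the pipelines are correct and calibrated under the stated design —
not that any real cohort's effect sizes are reproduced: PC variance
shares, F statistics and per-bin percentages of real horses depend on
real images, which this package does not ship.

## Numerical choices and degenerate inputs

* GPA: tolerance `1e-8` on consensus displacement, max 100 iterations,
  non-convergence flagged (`converged = FALSE`) with a warning, partial
  result returned. Degenerate (zero-size) configurations error.
* Classifier group order is fixed (A < B < C < D, 0 < 1) for
  deterministic reports; subset analyses run whole → time subsets →
  condition subsets.
* Zero residual SS in the shape ANOVA reports a boundary p with a
  warning; empty groups error.
* `compute_angle()` clamps the cosine into [-1, 1]; zero-length arms
  error.
* Ties in nearest-reference color classification break toward the cooler
  bin; the background color is unclassifiable by construction.
* Kruskal–Wallis on an all-tied sample errors (`degenerate ties`), and
  the thermal pipeline skips all-zero bins (e.g. the empty top bin before
  lunging) rather than testing a constant.
* Quantile convention: linear interpolation between order statistics
  (type 7), stated because the source does not fix one.

## Problem sizes used by the validation suites

The packaged suites run the type-I calibration at 2000 replicates of the
full 104-configuration null (isotropic noise, no group effect — the
stated null model, without horse-level heterogeneity), the power check at
500 replicates of the full generator's RB subset, the render→classify
round trip over 50 random fields plus the exhaustive 1001-step palette
sweep, and the Monte-Carlo ellipse coverage at 10^5 points. These sizes
keep the whole suite under a minute of simulation while leaving the
binomial error on a 0.05 rejection rate at ≈ 0.005.

## Known limitations

* The Goodall F is approximate under non-isotropic landmark variation;
  the permutation option is the robust alternative.
* Sliding of semilandmarks (minimizing bending energy or Procrustes
  distance along the curve) is out of scope; semilandmarks are treated as
  fixed points.
* The bundled palette is a synthetic stand-in; analyses of real exported
  thermograms must load the camera's palette for faithful binning.
* BMP rasters (the study's export format) are not read; convert to PNG
  losslessly.
* Repeated measures are compared as independent groups (the source
  design's choice); a mixed-effects treatment of the paired structure is
  deliberately not implemented.
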