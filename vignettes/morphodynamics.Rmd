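---
title: "Quantifying cell morphodynamics: methods and design notes"
author: "morphodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell morphodynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodyn)
```

This vignette documents the models behind `morphodyn`, the numerical
choices made where the field leaves them open, and what the synthetic-data
generator does and does not emulate. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

# The measurement model

## Shape measures

A segmented cell is a binary mask (one 8-connected component, pixel size
in µm). Twenty-one geometric measures summarise it: sizes (area,
perimeter, equivalent diameter, convex area and perimeter, Feret
diameters, axis lengths), dimensionless shape descriptors (form factor
`perimeter²/area`, circularity, solidity, convexity, extent, aspect
ratio, eccentricity, Feret ratio, boundary roughness) and backbone
descriptors (skeleton length, number of skeleton endpoints, curl). The
panel is configurable, but area, perimeter, form factor, aspect ratio,
solidity and curl are mandatory: they anchor the downstream analysis.

Three estimators deserve explanation, because naive pixel counting fails
the calibration bounds a shape panel must satisfy:

* **Perimeter.** A raw pixel-edge (crack) count overestimates smooth
  outlines by up to 4/π, and weighted chain-code counts still err by
  several percent with shape-dependent sign, which corrupts the form
  factor — a quantity whose floor (4π, attained by a disk) carries
  meaning. We therefore trace the outer boundary through pixel centres
  (Moore neighbourhood), remove the pixel staircase with a short Gaussian
  smoothing along the closed contour (σ = 1 sample, ±3 samples), and add
  the parallel-offset correction +π·pixel for the half-pixel gap between
  centre-traced and true outer boundary (offsetting a simple closed curve
  by d lengthens it by 2πd). The test suite pins a digital disk's form
  factor within 5% of 4π and a square's within 5% of 16; a pure
  multi-direction Crofton estimator, attractive in theory, fails the
  square bound at −11% and was rejected.
* **Solidity.** Convex area is the count of grid pixels inside the convex
  hull of the foreground pixel centres (exact integer arithmetic), so
  solidity is a pixel-count ratio and can be verified pixel-exactly
  against a brute-force hull rasterisation (see the test suite's oracle).
* **Skeleton and curl.** The backbone comes from Zhang–Suen topological
  thinning; spur branches shorter than 4 px (thinning end-fork artefacts)
  are pruned, and path length uses Kulpa's corrected step weights
  (0.948 / 1.340) rather than 1 / √2, removing the classic staircase
  inflation of digital line length. Curl is the longest straight span of
  the cell (maximum Feret diameter) divided by the skeleton length,
  capped at 1: a straight rod has curl 1, a semicircular arc 2/π. We use
  the Feret span rather than the moment-ellipse major axis because only
  the former reproduces the 2/π value for a semicircular band (the
  moment axis of that shape is 2.83·R, not 2·R) and keeps the "≈1 when
  straight" semantics exact. Blob-like masks whose skeleton collapses are
  assigned curl 1 by convention. Thinning runs in a canonical grid
  orientation (lexicographically smallest of the four rotations), which
  makes skeleton measures exactly invariant under 90° rotations.

Invariance expectations: all measures are exactly translation- and
90°-rotation-invariant; dimensionless measures are stable to a few
percent under resolution doubling and 45° rotation *for resolved, smooth
shapes*. Two caveats are intrinsic, not implementation artefacts:
`extent` uses the axis-aligned bounding box and cannot be rotation
invariant (a square's extent halves at 45°), and eccentricity is
ill-conditioned near circularity. Thin structures (≈ 2 px wide) are
genuinely altered by interpolated rotation; their accuracy is pinned by
analytic oracles instead.

## Segmentation and tracking

Segmentation is deliberately simple — Otsu global threshold, hole
filling, radius-1 opening, largest component — because the package's
focus is downstream of segmentation; learned segmentation and
touching-cell splitting are out of scope. Tracking is greedy
nearest-centroid linking with a `max_jump` gate (default 20 µm); links
beyond the gate terminate a track rather than guess.

# Phenotype classification

Four trainable phenotypes (AE, BB, FP, LA) are recognised; INT
(intermediate) is a valid dwell state but never a trainable class.
Features are standardized (the parameters live in the model), classes are
inverse-frequency weighted, and probabilities come from pairwise-coupling
calibration (SVM) or vote fractions (random forest). The definite-call
rule is strict: label = argmax class iff its calibrated score exceeds
0.6; a score of exactly 0.6 is INT. Because scores are renormalised to
sum to 1, at most one class can ever be definite.

A held-out stratified split (20%) reports accuracy before the final model
is refit on all data. On the package's separable synthetic archetypes
this accuracy is ≥ 0.9 by construction — an internal bar, not a claim
about any real labelled corpus, whose published accuracies are properties
of data we do not have.

For visualisation, an exact (dense) t-SNE embeds the standardized shape
space in 3-D; no R t-SNE implementation ships in the package's dependency
set, so the embedding (perplexity search, early exaggeration, adaptive
gains) is implemented here. Out-of-sample cells are placed into the
*frozen* map by minimising their own Kullback–Leibler contribution
(BFGS from the median embedded coordinate of the 10 nearest training
neighbours); a pure k-NN placement is available as a fast fallback. The
literature's "modified t-SNE" projection is not fully specified, so this
is a declared interpretation; its contract is tested behaviourally
(training points re-project onto their stored coordinates, duplicates
coincide, interpolated points stay inside their class's neighbourhood).

# Mesoscale dynamics

The phenotype series sampled at `dt` (default 0.25 h, i.e. 4 frames/h) is
modelled as a continuous-time Markov chain (CTMC).

* **Occurrence fractions** are frame counts; CIs come from a cell-level
  bootstrap (default 1000 iterations) because frames within a cell are
  correlated — the resampling unit is always the whole track.
* **Dwell times** are maximal runs × `dt`; runs touching a track boundary
  are censored and excluded from means (their completion was not
  observed). A fully monomorphic track therefore contributes no completed
  episode and an `NA` mean. Note that the *observed* mean dwell of an
  exponential state with exit rate λ is `dt / (1 − exp(−λ·dt))`, not 1/λ:
  sampling discretises the run length into a geometric variable. Tests
  and consistency checks compare against this corrected expectation.
* **Transition rates** default to the count estimator
  `r(i→j) = N(i→j) / T_i` in h⁻¹. At finite `dt` fast chains are
  under-counted (double jumps within a frame are invisible — a cell
  passing i→k→j registers i→j); the optional `method = "matrix_log"`
  estimates the per-frame stochastic matrix and takes its principal
  eigen-logarithm over `dt`, which removes this bias when the per-frame
  matrix is well estimated. Negative off-diagonals arising from noise are
  clamped to zero and the raw estimator is the fallback when the
  eigenvalues preclude a real logarithm.
* **INT handling** defaults to an explicit 5-state matrix. The `bridged`
  mode collapses INT runs of ≤ 2 frames between definite states i and j
  into a direct i→j event, splitting the INT time equally between i and
  j — the convention matching published 4-state matrices where switching
  proceeds "via" brief intermediate frames. Both conventions are one
  argument apart because the field's reports do not state which was used.
* **Probability fluxes** `J_ij = p_i r_ij − p_j r_ji` are antisymmetric by
  construction; the detailed-balance score `max|J| / max(p_i r_ij)` is 0
  for an equilibrium-like landscape and approaches 1 for a strongly
  driven cycle.

# Phenotype-coupled motility

Steps span exactly one `dt` (15 min); multi-interval steps are out of
scope. Each step's category is the ordered coarse-class pair at its two
frames (`ME` = FP+LA, `AM` = AE+BB, plus INT), following the convention
that a step starting amoeboidal and ending mesenchymal is an "AM-ME"
step. Magnitudes are fitted by closed-form log-normal maximum likelihood;
the reported `m` and `σ²` are the distribution's mean and variance on the
natural µm scale (`exp(μ + s²/2)` etc.), with the log-scale parameters
also returned, because µm-scale moments are what sit next to µm²-scale
MSDs; CIs are nonparametric bootstrap. Zero-magnitude steps are excluded
(log undefined) and counted. A log-likelihood difference against a
Gaussian fit of the same data provides the model-comparison diagnostic.
Categories with fewer than 30 positive steps are reported as
insufficient.

Conditional MSDs use only frame pairs inside maximal constant-class
segments, each segment entering the ensemble as its own track; the
default lag range is the 90th percentile of segment spans (capped by the
quarter-median-track-span rule that governs all time-averaged MSDs here),
so the fitted slope is supported by a non-negligible share of segments.
Effective diffusivity is `slope / (2·dims)` with `dims = 2` for projected
centroid motion: an MSD slope of 24 µm²/h means 6 µm²/h per spatial
dimension. The occurrence-weighted average of conditional MSDs is the
motility that dwell behaviour alone would predict; its shortfall against
the full-trajectory MSD measures how much switch-coupled steps add.

# Spatial analysis at an ECM interface

Events (label changes between consecutive frames; dwell events when the
label repeats) are located at the *midpoint* of their frame pair — an
unbiased convention for symmetric motion. A 1-D Gaussian kernel with
bandwidth 10 µm (grid spacing bandwidth/5, both configurable) estimates
the event density `P(i→j, x)` normalised to events per hour and the cell
density `M(x)` normalised to mean cells per frame; the spatial frequency
is the pointwise ratio `R = P / M` wherever `M` exceeds 5% of its
maximum (the density floor guards the ratio where almost no cells were
observed; flagged grid points carry `NA`, and no division occurs there).
The identity `R·M = P` holds to machine precision on valid points by
construction and is asserted in the tests. Per-layer summaries reuse the
mesoscale estimators on side-filtered data: fractions and dwell times use
the side of each frame, transition counts the side of the pair midpoint.

# The synthetic-data generator

The generator exists so every stage has ground truth. It emulates:

* **Archetype masks** — star-convex bodies (ellipse + low-order Fourier
  boundary noise) with phenotype-specific protrusions: hemispherical
  bumps (BB), sharp capsule spikes (AE), long thin pole spikes on an
  elongated body (FP), one fan-shaped lobe (LA). Spikes are rendered as
  constant-width capsules so they stay resolvable to the tip; geometry
  that rasterises below connectivity raises an error naming
  `protrusion_width`. Masks are deterministic in (parameters, seed).
* **Phenotype-switching tracks** — an exact Gillespie CTMC over the five
  dwell states observed at `dt`, with 2-D isotropic steps whose
  magnitude is log-normal per step category. The default generator's
  stationary INT occupancy is about 10%, and the default step model is
  calibrated so AM dwellers have D ≈ 6 µm²/h per dimension, ME dwellers
  ≈ 19 µm²/h, switch-coupled steps are larger than dwell steps, and the
  ME→AM step variance is about twice the AM→ME variance — the study
  conditions the downstream estimators are validated against.
* **Two-layer populations** — per frame, the chain evolves under the
  generator of the layer containing the cell's current x; initial
  positions scatter uniformly across ±150 µm of the interface.
* **Rendered movies** — one mask per frame at the track's centroid on a
  shared canvas (20% margin; canvases above 2000 px are refused with the
  required size). INT frames render as the previous definite archetype
  with protrusion length halved, a deliberate convention that makes
  intermediate-state handling testable.

All randomness descends from one seed through a counter-based splitting
hash (`derive_seed`), so sub-streams are independently reproducible.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: optical artefacts (PSF, shot noise,
defocus), touching or overlapping cells, segmentation failure modes,
persistent or fibre-aligned motion (steps are isotropic and memoryless,
so simulated centroids are diffusive, `α ≈ 1`, whereas real 3-D migration
is reported slightly superdiffusive; the package can measure such an
exponent but the generator does not produce it), non-exponential dwell
processes, and any molecular readout. Shape-space subdiffusion is
emulated separately by a mean-reverting (Ornstein–Uhlenbeck) series whose
closed-form MSD `2v(1 − exp(−τ/θ))` anchors the exponent tests.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `dt` | 0.25 | h | 4 frames/h imaging cadence |
| `pixel_size` | 1 | µm/px | typical confocal sampling at 20× |
| `threshold` | 0.6 | — | strict definite-call cutoff; ties → INT |
| `n_boot` | 1000 | — | bootstrap iterations for every CI |
| `bandwidth` | 10 | µm | interface kernel; ≈ one cell diameter |
| `density_floor` | 0.05·max(M) | — | guards R = P/M in unsupported regions |
| `bridge_max` | 2 | frames | INT runs this short can be bridged |
| `max_jump` | 20 | µm | linking gate ≈ max plausible 15-min step |

# Problem sizes

The test suite validates estimator consistency at deliberately modest
scales chosen so the whole suite runs in well under an hour on one CPU:
rate recovery on ≈ 2000 state-hours of simulated chain (25 cells × 80 h),
classifier fixtures of 60 masks per class, embeddings of 240 points,
two-layer populations of 60 cells × 24 h, and 10-seed replicates for
fraction-of-seeds properties. `scripts/acceptance.R` uses 100 cells ×
40 h (4000 cell-hours) for the motility statistics, the scale of a full
recording campaign. Statistical assertions are phrased in standard
errors or bootstrap intervals so they remain meaningful at these scales.

# Known limitations

* The count rate estimator is biased low for states with mean dwell near
  `dt` (the INT state under the default generator); the matrix-logarithm
  correction removes most of it but needs enough data per row.
* Skeleton-based measures (skeleton length, endpoints, curl) are the
  least resolution-robust of the panel; below ≈ 10 px of cell diameter
  they are dominated by discretisation, and the form-factor floor 4π
  holds only for masks resolved to that level.
* The t-SNE projection of far-out-of-distribution points is an
  extrapolation; its locality guarantees only hold near the training
  manifold.
* Dwell-time inference uses censoring-by-exclusion, not a survival
  estimator; heavily censored data (tracks much shorter than dwells)
  will under-represent long dwells.
* No hidden-state deconvolution is attempted: rates are estimated from
  the observed label sequence, not from an expectation-maximisation fit
  of an underlying faster chain.
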