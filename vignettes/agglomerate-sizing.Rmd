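---
title: "Measuring nanoparticle agglomerate dispersion from dark-field STEM images"
author: "agglomsizer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nanoparticle agglomerate dispersion from dark-field STEM images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agglomsizer)
```

## Scope and model of the data

`agglomsizer` quantifies the dispersion state of nanoparticles suspended in
aqueous (often biological) media from dark-field STEM images of
plunge-frozen, vacuum-dried aliquots. In this imaging mode scattering
objects are bright on a dark support film. The unit of measurement is the
*agglomerate*: a cluster of primary particles behaving as one dispersed
unit, with single particles counted as minimal agglomerates. The package
covers everything from raw image to distribution statistics; it does not
control the microscope, prepare samples, or model electron optics.

Three image phenomena drive the design:

* **Uneven illumination.** Beam and detector response vary smoothly across
  the field, multiplying the signal. Left uncorrected it confounds any
  intensity-based classification.
* **Focal halos.** At the low magnifications needed for large fields of
  view, small focus variations push contrast beyond the true particle edge,
  so a faithful segmentation of the *bright region* overestimates object
  size.
* **Salt precipitates.** Media salts crystallize on the grid at gray levels
  overlapping the particles. No global intensity threshold can separate
  them; their *texture* can.

## The synthetic scene generator

No reference image data ship with the package, so a seeded generator
(`scene_spec()`, `generate_scene()`) produces scenes with exact ground
truth. It is phenomenological — it renders the three artifacts above, not
the physics that causes them.

* Agglomerates are unions of 1–4 overlapping disks per object (a single
  disk is the single-particle case), rendered at a uniform gray level.
  Object diameters are lognormal; the stock condition uses a median of
  600 nm with shape σ = 0.35 at 30 nm/px — a moderately agglomerated
  dispersion of the kind seen for iron-oxide particles in serum-free
  culture media, at the pixel scale implied by a ~30 µm horizontal field
  width. Objects are placed by rejection sampling (at most 10,000 attempts,
  then an error) so that no two objects or their halos touch: overlap is
  forbidden rather than merged because merged objects would have ambiguous
  per-object truth.
* Halos are annuli produced by `halo_width` (default 2) rounds of 3×3
  dilation around each object, rendered at `halo_intensity_fraction`
  (default 0.3) of the object contrast. The width is a calibration choice,
  not a measurement: it is set so that an uncorrected segmentation
  measurably overestimates size.
* Salts are convex-ish polygons at a mean gray level (default 0.7) close to
  the agglomerate level (0.75), with per-pixel multiplicative speckle
  (σ = 0.25). Intensity histograms of the two classes therefore overlap,
  which is precisely what makes global thresholding fail by design; only
  texture separates them.
* A smooth multiplicative illumination ramp (relative amplitude default
  0.2, random orientation) and additive Gaussian noise (σ = 0.02 gray
  levels) are applied last; ground truth reflects the clean geometry. A
  Poisson noise model was considered and left out — nothing in the
  workflow's assumptions characterizes the detector noise, and the additive
  model is the simpler default.
* Gray levels are normalized to [0, 1]; 16-bit TIFF export scales
  accordingly.

Ground truth records the class map (background / agglomerate / salt), the
per-object label map, the halo annulus, and a per-object table whose Feret
diameters and areas are computed from the rendered raster — so generator
and measurement share one geometric convention and "truth" is exactly what
a perfect segmenter would see before halos and noise.

What the generator does **not** emulate: partial-focus blur gradients,
agglomerates touching each other, non-convex salt shapes growing around
particles, carbon-film texture, charging streaks. Passing tests on these
scenes therefore demonstrates the pipeline's mechanics — they do not prove
performance on any particular real dataset.

`generate_scribbles()` emulates sparse manual annotation: a fraction of
*interior* pixels of each class is sampled, salts are deliberately labelled
`background` (the two-class convention), and halo pixels — ambiguous by
construction — are never sampled. `simulate_blot_subsample()` models the
object loss of the pre-freezing blotting step as independent thinning.

## Illumination correction

`estimate_illumination()` fits, at every pixel, a first-order polynomial to
the image under a Gaussian window (default scale = image width / 8),
weighting out bright pixels: first by a global rank cut (default 75th
percentile), then — because a fixed cut bites into background noise
wherever the background approaches it — re-masking relative to the first
fit (keep pixels within 4 robust s.d.) and refitting. The normal equations
are assembled from separable convolutions, so the cost is a handful of
smoothing passes. The local *plane* fit (rather than plain smoothing) is
what makes linear ramps reproduce exactly at image borders, where
convolution with reflective padding is biased.

Correction divides by the field and rescales so the median intensity is
preserved. Division rather than subtraction because dark-field shading is
gain-like; the choice is recorded in the function's contract, and the field
itself is returned so a subtractive variant can be composed by the user.
Correction is applied per image: each image carries its own field.

## Pixel classification

A probability random forest (ranger, 100 trees, unlimited depth, balanced
case weights, fixed seed, single-threaded for determinism) is trained on
the feature vectors of the scribbled pixels only. Features per scale
σ ∈ {0.7, 1, 1.6, 3.5, 5, 10} px: Gaussian-smoothed intensity, gradient
magnitude, Laplacian, the two structure-tensor eigenvalues (smoothed at the
same σ), the two Hessian eigenvalues, and local variance — the conventional
multi-scale bank of interactive pixel-classification tools; the scale
ladder and forest size are defaults, surfaced in the API. Derivatives are
central differences of the smoothed image, so every derivative feature of a
constant image is exactly zero.

Exactly two classes are used, with salt trained as background. Training
images are a small subset of the dataset (the pipeline default is the first
two images); nothing in the workflow specifies how training images should
be chosen, so the choice is positional and documented as unvalidated.
Models serialize to a versioned RDS so training and batch prediction can
run as separate steps.

**Known limitation.** The forest separates salt from agglomerate largely
through local-variance features. Object *edge* pixels also carry high local
variance, so on salt-bearing scenes the decision boundary sits one to two
pixels inside the true edge: object counts and detection precision remain
high, but sizes bias low by a few percent more than on salt-free scenes.
The measurement-accuracy claims in the tests are therefore made on
salt-free dispersions; the salt scenes support the detection-precision
claim.

## Object measurement

* **Segmentation**: probability ≥ 0.5 (the symmetric two-class decision),
  8-connected components (diagonal contact keeps an agglomerate whole),
  minimum object size 4 px (a 2×2 object). Thresholds are parameters;
  these are the defaults.
* **Coordinates**: (row, col), origin top-left; a pixel occupies its unit
  square, so object extent includes pixel extent and a 1-px object has
  Feret diameter √2 px. This corner convention is applied uniformly,
  including to ground truth.
* **Feret diameter**: rotating calipers over the convex hull of the pixel
  corner points; because corners lie on the integer lattice the result
  equals the brute-force maximum over all corner pairs exactly (this is a
  test). Max-Feret is implemented — the common convention — rather than a
  mean over orientations.
* **Erosion** (`erode_objects()`): each object independently, n rounds of
  3×3 binary erosion. Per-object application means separated labels can
  never merge; objects emptied by erosion are dropped and logged, not
  restored — restoring them would reintroduce exactly the halo bias the
  step removes. For a halo produced by k dilation rounds, k−1 residual
  rounds remain after eroding once, so a 1-px erosion removes at least half
  of a 2-px halo's Feret bias; the Minkowski-support argument makes the
  ≥ 50% reduction exact per object, and the shift of the maximizing
  direction adds a small margin.
* **Perimeter**: a Moore boundary walk over pixel centres (a dedicated
  tracer with Jacob's stopping criterion — generic tracers in the
  supporting libraries mis-trace diagonally connected shapes), with
  orthogonal steps weighted 1 and diagonal steps weighted
  1 + (π/4 − √2/2)/(1 − √2/2) ≈ 1.2673 — calibrated so digitized circles
  are unbiased on average while axis-aligned rectangles stay exact — plus π
  for the half-pixel outward offset from centres to the true boundary
  (offsetting a closed curve of turning number 1 by r adds 2πr). Single
  pixels use their crack perimeter 4. Resulting form factors: ~0.96 for a
  20-px-radius disk, → π/4 for large squares, ≤ 1.1 for every object
  tested.
* **Moment axes**: ellipse-equivalent convention, 4·√λ of the second
  central moments with the per-pixel 1/12 term. For compact objects
  Feret ≥ major ≥ minor holds; strongly concave thin shapes can violate
  the first inequality (a property of the ellipse convention, documented
  rather than clipped).

## Distribution statistics

For measured Feret diameters *d₁…dₙ*:

* number mean = mean(*d*), SEM = sd/√n, median, IQR;
* volume-averaged diameter = (mean(*d*³))^(1/3): each object is treated as
  a sphere of diameter *d* (a stated simplification), volumes are averaged,
  and the result converted back to a diameter — the π/6 cancels. An
  alternative reading, the volume-weighted mean diameter Σ*d*⁴/Σ*d*³, is
  available behind `mode = "weighted_mean"` but is not the default: the
  mean-volume construction is the literal form of "average the volumes,
  then convert";
* intensity-weighted mean = Σ*d*⁷/Σ*d*⁶, simulating how a light-scattering
  measurement (intensity ∝ *d*⁶) weights the same objects. The power-mean
  chain number ≤ volume ≤ intensity holds for every sample, with equality
  iff monodisperse.

Group comparison uses the Welch unequal-variance t-test
(`stats::t.test(var.equal = FALSE)`): the unpaired two-sample setting does
not license equal variances, and Welch reduces to Student when they are
equal. Degenerate zero-variance inputs are defined explicitly (equal
constants: t = 0, p = 1). No multiple-testing correction is applied to the
single test; the CLI's batch mode reports Holm-adjusted p-values alongside
raw ones as a flagged extension. Histograms use fixed-width half-open bins
[lo, hi) anchored at multiples of the bin width; edge values go up.

## Validation

`match_objects()` computes the IoU of every overlapping object pair and
matches greedily in descending IoU (ties broken by ref id then test id),
with a minimum IoU of 0.2 for a valid match. Greedy matching is used
because it is deterministic, order-independent given the strict sort, and
needs no tuning; the per-object Jaccard of the matched pairs, summarized as
mean ± sd, is the headline agreement number, with the pixel-level count
ratio reported alongside. `threshold_baseline()` is the comparison point
for the learned classifier: a global threshold chosen by exhaustively
maximizing pixel F1 against ground truth — an oracle no practical
thresholding heuristic can beat, which makes the classifier-vs-threshold
comparison conservative.

## Reproducibility and problem sizes

Every stochastic step (scene placement, scribble sampling, forest training)
is seeded; the pipeline derives per-stage, per-image seeds from one master
seed, so reruns are byte-identical down to the measurement CSVs. The test
suite and the acceptance script run on 256×256 px scenes with ~12 objects
each — about 5 s per classifier train/predict cycle on one CPU — using 5–6
scenes per property and 10 seeds for the salt-rejection comparison; these
sizes give ~70 objects per end-to-end run, enough for the count-ratio,
mean-recovery and IoU properties to be stable at the tolerances tested.

## Limitations

* Touching agglomerates are measured as one object; no watershed splitting.
* Sizes are 2-D projections; no 3-D shape recovery, and the sphere
  assumption enters the volume and intensity weightings.
* The salt/edge variance interaction biases sizes low on salt-heavy fields
  (see above).
* The generator's halos and salts are stylized; real focal halos are
  anisotropic and real precipitates less regular.
* Eight shape attributes are implemented; further descriptors (convexity,
  solidity, orientation, …) are out of scope.
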