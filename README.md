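# agglomsizer

Automated sizing of nanoparticle agglomerates in dark-field STEM images.

## The problem

How nanoparticles disperse in a liquid — as single particles or as
agglomerates, and of what size — controls dose, uptake and toxicity in
nanomedicine and nanotoxicology studies. Dynamic light scattering (DLS), the
routine sizing tool, struggles in biological media: scattering intensity
grows as the sixth power of particle diameter, so a few large agglomerates
drown out the rest, and dissolved media components add confounding signal.
Electron microscopy of plunge-frozen, vacuum-dried aliquots images the
dispersion directly, but quantifying hundreds of images by hand is
impractical, and simple intensity thresholding fails when salts from the
medium precipitate onto the support grid at gray levels overlapping the
particles.

`agglomsizer` implements the automated analysis side of this workflow for R:

1. **Illumination correction** — a rank-masked locally weighted plane fit
   estimates the smooth multiplicative background of each image, which is
   divided out.
2. **Pixel classification** — a random forest trained on sparse two-class
   scribbles ("agglomerate" / "background"; salts are labelled background)
   over a multi-scale filter bank (Gaussian-smoothed intensity, gradient
   magnitude, Laplacian, structure-tensor and Hessian eigenvalues, local
   variance at σ ∈ {0.7, 1, 1.6, 3.5, 5, 10} px) yields a per-pixel
   agglomerate probability map. Texture, not intensity alone, is what lets
   the forest reject salt precipitates that defeat any global threshold.
3. **Measurement** — probability maps are thresholded at 0.5, 8-connected
   components become objects, each object is eroded by 1 px to strip the
   focal halo that otherwise inflates outlines, and per-object descriptors
   are reported in physical units: maximum Feret diameter *d* (rotating
   calipers over the convex hull of pixel-corner points), area *A*,
   boundary-walk perimeter *P*, form factor 4π·*A*/*P*², moment-ellipse
   major/minor axes, equivalent circular diameter.
4. **Statistics** — number-weighted mean ± SEM, the volume-averaged diameter
   (mean(*d*³))^(1/3), and the simulated light-scattering intensity-weighted
   mean Σ*d*⁷/Σ*d*⁶ that shows how a *d*⁶-weighted technique like DLS sees
   the same dispersion; Welch two-sample comparison between datasets.
5. **Validation** — greedy per-object Jaccard (IoU) matching between two
   segmentations, plus an oracle global-threshold baseline (threshold chosen
   by exhaustive F1 sweep against ground truth) for the salt-rejection
   comparison.
6. **Synthetic scenes** — a seeded generator of dark-field scenes with full
   ground truth (bright multi-disk agglomerates, focal halo annuli, speckled
   salt polygons, smooth illumination gradients, shot noise) used for
   benchmarking and testing; deposited image data are not required.

## Worked example

```r
library(agglomsizer)

sp <- scene_spec(seed = 42)            # 256x256 px @ 30 nm/px, 12 agglomerates
sc <- generate_scene(sp)
img <- correct_illumination(sc$image, estimate_illumination(sc$image))
scr <- generate_scribbles(sc$truth, fraction = 0.05, seed = 1)
model <- train_pixel_classifier(img, scr, seed = 1)
mask <- erode_objects(segment(predict(model, img), threshold = 0.5), n_px = 1)
rec <- measure_all(mask, img)

number_summary(rec$feret_nm)
volume_average_diameter(rec$feret_nm)
intensity_weighted_summary(rec$feret_nm)
agreement_summary(match_objects(sc$truth$object_map, mask$labels))
```

Output:

```
<pixel_classifier> 100 trees, 48 features @ scales {0.7, 1, 1.6, 3.5, 5, 10}, labels: agglomerate=230, background=2754, train acc 1.000
<label_mask> 256 x 256 px, 12 objects (8-connectivity)
<size_distribution> number-weighted, n = 12: mean 695 nm (SEM 75), median 681, IQR 443.4
volume-averaged diameter: 776.3 nm
intensity-weighted mean: 999.4 nm
ground-truth number mean: 731.3 nm
validation: 12/12 matched, mean IoU 0.88 +/- 0.07, count ratio 1.00
```

All 12 true objects are found (count ratio 1.00) with mean per-object IoU
0.88; the machine number mean (695 nm) sits within 5% of the ground truth
(731 nm). The three weightings of the *same* diameters — 695 nm
(number), 776 nm (volume), 999 nm (intensity) — illustrate why a DLS-style
intensity-weighted measurement reads ~40% above the number mean for this
polydisperse sample.

On a salt-bearing scene, the trained classifier keeps object-level precision
high while the *best possible* global threshold cannot:

```
salt scene: ML object precision 0.92 vs best-threshold 0.71
```

A one-call pipeline (`run_pipeline(pipeline_config(...))`) chains all stages
from a single seeded config and writes images, probability maps, masks,
measurement/summary/validation CSVs and a JSON manifest. A thin CLI wrapper
lives at `inst/cli/agglomsizer.R` (`run`, `synth`, `correct`, `train`,
`predict`, `measure`, `stats`, `validate` subcommands).

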