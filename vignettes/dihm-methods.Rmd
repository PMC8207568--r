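---
title: "From interference pattern to classified plankton: the dihm workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From interference pattern to classified plankton: the dihm workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dihm` implements a complete digital in-line holographic microscopy (DIHM)
workflow for plankton: a physics-based hologram simulator with exact ground
truth, numerical wavefield reconstruction of a z-stack through the sample
volume, detection and autofocus selection of in-focus objects, a
classification-ready dataset builder, a compact trainable classifier, and
threshold/probabilistic/ranked evaluation. This vignette explains the
models behind each stage, the parameters that matter, the numerical choices
made, and what the synthetic experiments do and do not demonstrate.

## The optical model

A point source (a 405 nm laser coupled to a single-mode fiber) emits
spherical waves through a flow cell; objects in the sample space scatter
part of the wave, and the scattered and unscattered components co-propagate
to a monochrome sensor 54 mm from the source, where their interference is
recorded as a 2048 x 2048, 8-bit hologram. Because reference and object
waves share one path, the setup is lensless (Gabor holography) and the full
3-D sample volume is encoded in a single frame.

All lengths in `dihm` are micrometres. A geometry is a plain record:

```{r}
library(dihm)
g <- optical_geometry()      # 405 nm, 54 mm, 2048 px, 5.5 um pitch,
g                            # 15 mm sample space, 50 um z-step
```

Two derived quantities drive everything:

* **Magnification.** An object at distance `z` from the point source is
  magnified on the sensor by `M = L / z`, with `L` the source-to-camera
  distance (`magnification()`).
* **Effective distance.** By the Fresnel scaling theorem, the spherical-wave
  recording equals a *plane-wave* hologram of the same object taken at
  `z_eff = z (L - z) / L`, magnified by `M` (`effective_distance()`). This
  turns point-source holography into ordinary plane-wave diffraction on a
  regular grid.

The sensor pixel pitch is an instrument property the optical layout does
not fix; it is a configuration value with a documented default of 5.5 um, a
typical machine-vision CMOS pitch. Every physical conversion (object pixel
size `pitch / M`, ROI diameters, centroid coordinates) reads it from the
geometry object; nothing hard-codes it.

### Forward simulation

`simulate_hologram()` applies each phantom object as a thin disc-shaped
transmittance mask (antialiased edges; transmission 0 = opaque, optional
phase shift) and carries the field between planes and to the sensor with
the angular-spectrum method: the field's FFT is multiplied by
`exp(i 2 pi d sqrt(1/lambda^2 - fx^2 - fy^2))` and transformed back.
Evanescent frequencies (beyond `1/lambda`) are zeroed, and the kernel is
additionally capped at the standard band-limiting frequency
`1 / (lambda sqrt((2 d df)^2 + 1))` per axis, without which the sampled
kernel aliases at the large propagation distances this geometry produces
and wraparound copies contaminate the field.

All propagation happens in *sensor coordinates*: each plane's effective
distance is expressed as `z_eff M^2 = L (L - z) / z` and the grid pitch is
the sensor pitch. For a single object this is algebraically the same
Fresnel-scaled problem; for several objects at different depths it provides
the one shared frame in which the sequential mask-multiply-propagate pass
is self-consistent (each object still focuses at its own depth, and
occlusion is preserved qualitatively, as in real volumes). A
first-Born-style sum of single-object holograms reproduces the joint
simulation within a few percent of the fringe amplitude for weak objects —
one of the package's property tests.

Sensor effects are layered on in the order they occur physically:
a radial Gaussian illumination falloff (`vignette_field()`, brightest on
the optical axis, attenuating to the edges), Poisson shot noise with a
configurable mean photon count (default 2000, about 2% relative noise —
the dominant sensor noise, controlled by one parameter), and quantization
to `2^bit_depth` gray levels with the mean intensity anchored mid-scale.
Quantization is the only irreversible step: with it disabled, write/read
round-trips are lossless. Polarization, partial coherence, multiple
scattering and fixed-pattern sensor noise are out of scope.

## Reconstruction

`background_normalize()` converts intensity to a zero-mean contrast field,
either against an explicit object-free reference frame (exact) or against a
Gaussian low-pass of the hologram itself, which also removes the vignette.
The low-pass is FFT-based with mirror extension, so image borders are not
averaged against their wrapped-around opposites. Its scale `sigma`
(default `sensor_pixels / 8`) trades off two failure modes: too small and
it absorbs the low spatial frequencies of large objects (which visibly
biases focus metrics); too large and it under-tracks the illumination
envelope. The default favors object preservation; for envelope flattening
of object-free frames a smaller sigma (e.g. `n/32`) tracks the vignette's
curvature to below 1%.

`reconstruct_plane()` re-adds the unit reference wave, apodizes the
contrast with a cosine border (default 16 px, disableable) to suppress FFT
wraparound, and back-propagates by the plane's sensor-frame effective
distance. The recorded quantity is the field *amplitude* — absorbing
plankton appear dark on a bright (~1) background, matching reconstructed
amplitude imagery — with intensity available via `mode = "intensity"`,
since reconstruction software differs on this point. Each plane carries
its own `object_pixel_size = pitch / M(z)`.

`reconstruct_stack()` schedules planes over the half-open interval
`[z_min, z_max)` at the configured step — 50 um over a 15 mm sample space
gives exactly 300 planes; all z are handled in integer micrometres so
schedules are exact — and reuses the contrast FFT across planes, so a
stack costs one forward FFT plus one kernel multiply and inverse FFT per
plane.

The sample-space origin `z_min` relative to the instrument window is not
an optically determined quantity; it is configurable with a default of
2 mm.

## Detection

Per plane, `segment_plane()` applies a global Otsu threshold: the spec of
the histogram is fixed at 256 bins spanning the plane's `[min, max]`, the
split maximizing between-class variance is chosen, and ties go to the
lowest threshold. Dark polarity is the default (absorbing plankton on a
bright background); bright is available. Components are labeled with
8-connectivity so thin diagonal structures — setae, chains — are not
split. Components under 4 px are discarded as salt noise. One guard
reflects how global thresholds actually fail: on planes where every
object is far out of focus the amplitude histogram is unimodal ripple and
Otsu floods a large fraction of the field; if foreground exceeds
`max_fill` (default 20%) of the plane, the plane is treated as carrying no
separable objects. Local adaptive thresholding is deliberately out of
scope.

`extract_rois()` reports, per component, the axis-centered physical
centroid (pixel centroid relative to the grid center, scaled by the
plane's object pixel size — this axis-relative convention is what stays
put across planes for one object, which cross-plane clustering relies
on), the half-open pixel bounding box, the area, the mean amplitude, and
the equivalent diameter `object_pixel_size * 2 sqrt(area / pi)`.
The size gate keeps equivalent diameters in the closed interval
20–2000 um — read as inclusive bounds — spanning micro- to mesoplankton;
whether an instrument gates on equivalent diameter, major axis or bbox
size is unspecified in the field, and equivalent diameter was chosen.

## Cross-plane clustering and autofocus

One physical object is detected on many consecutive planes. `cluster_rois()`
groups detections with DBSCAN over the 2-D lateral centroids (x, y in um);
z is excluded because the same object holds its lateral position across
planes. Core points have at least `min_samples` neighbours (self included)
within `eps`; clusters are connected components of the core-point graph;
border points join the nearest core's cluster; noise is returned
separately, never dropped silently, and the partition is invariant to
input order. `eps = 10 um` and `min_samples = 2` are package defaults —
assumptions, as no reference values exist — and both are configurable.

`vollath_f4()` is the autocorrelation focus measure
`F4 = sum I(x,y) I(x+1,y) - sum I(x,y) I(x+2,y)`, computed along x with
both sums restricted to the common support of the two shift terms, so a
constant image scores exactly 0 (the textbook ranges, where the first sum
has one extra column, are available behind `convention = "naive"`). F4 is
translation-invariant for interior content and scales as the square of
intensity.

`select_focus()` picks, per cluster, the member plane with the highest F4.
Because F4 is an unnormalized sum, scores are only comparable over windows
of equal size, and detected bounding boxes dilate strongly with defocus;
members are therefore scored through a *common* window — the padded
bounding box (default pad 8 px, fringe context helps) of the cluster's
most compact member, re-centered per member — the classic fixed-window
z-stack autofocus. Exact ties break toward the lowest z, so selection is
deterministic. One focused object per cluster survives; the rest of the
cluster is discarded.

## Desk-scale experiments and what they show

Grids of 2048 x 2048 are wasteful for testing, but simply cropping the
sensor is wrong: depth of field scales as `lambda / NA^2` with
`NA = N pitch / (2L)`, so a 512-px sensor at the full 54 mm geometry
cannot localize depth to 50 um no matter how good the software is.
`scaled_geometry(4)` instead shrinks sensor, source distance and sample
space together (512 px, 13.5 mm, 3.75 mm sample space, 75 planes),
preserving the instrument's NA (~0.10), lateral resolution, and depth of
field exactly. The closed-loop experiment — 20 random single-disc scenes
(60–120 um discs, random positions, shot noise and vignette on),
full pipeline, fixed seed — recovers one object per scene with a median
depth error under one 50 um step. This validates the geometry,
propagation, normalization, detection, clustering and autofocus chain
end-to-end against ground truth, which no real dataset can provide. What
it does not show: robustness to real plankton morphology, motion blur,
turbid water, or dense scenes with overlapping fringes.

## Dataset construction

`standardize_crop()` scales the longest side to 128 px (bilinear),
preserves aspect ratio, and centers the result on a 128 x 128 canvas
padded with the median of the crop's border ring, which matches a
holographic background far better than zero; the operation is idempotent.
`split_records()` partitions each class 50:10:40 into train/validation/test
with largest-remainder rounding (ties in train, val, test order); classes
of at least 3 get one member per split, smaller classes go to training
with a warning. Splitting happens *before* augmentation so augmented twins
never straddle splits — the ordering that prevents leakage.
`augment_records()` then grows train/validation threefold: each image
yields itself, a horizontal flip and a vertical flip ("rotated
horizontally, vertically" is read as mirror flips, the common reading in
augmentation practice), the flips additionally translated by a seeded
uniform shift up to 10% per axis. Test records are never augmented, and a
provenance column records every derived image's source.
`stratified_kfold()` assigns folds so per-class counts differ by at most
one and per-class remainders go to the least-filled folds, making fold
totals exactly equal whenever the pool divides by k — a 7215-record pool
with the bundled 19-class proportions (`holosea_taxa_counts()`) yields
validation parts of exactly 1443 and training parts of 5772.

`synthetic_gallery()` generates the desk-scale stand-in for plankton
taxa: discs, annuli, rods, chains of small cells, spirals, and an
incoherent-speckle "noise" class mirroring the artefact-filter class used
in curated holographic datasets. Objects are dark (~60/255) on a bright
(~200/255), lightly noisy background with randomized size, orientation
and position; contrast was set once so that a plain linear probe on raw
pixels separates disc from rod (verifying learnable signal), and class
counts can be made deliberately imbalanced. These shapes exercise the
pipeline's bookkeeping and the classifier's capacity for morphology; they
do not emulate the texture, transparency or intra-class variability of
real plankton, so classifier scores on the gallery are an upper bound,
not a forecast, for real data.

## Classifier

`build_model()` under the default `scratch_small` mode builds the
package's compact reference CNN: a 2x average-pool stem — chosen so the
finest class-discriminating feature in the gallery (the inter-cell gap of
a chain, a few pixels) stays above the conv stack's Nyquist limit —
followed by three conv(3x3)/batch-norm/ReLU/max-pool blocks of 8, 16 and
32 channels, global average pooling, dropout 0.3, and a softmax head
(default 19 classes). Training (`train_fold()`) minimizes cross-entropy
with Adam at learning rate 0.01, batch size 32, 20 epochs, reducing the
rate by a factor of 10 when the loss fails to improve on the best-so-far
by 1e-3 for five epochs (strict comparison, as in the reference
reduce-on-plateau implementations; the patience counter resets on
reduction, so the rate history is a non-increasing step function).
Batch-norm running statistics use momentum 0.9 — the running-statistics
reading of "momentum in batch normalization layers". Inputs are 128 x 128,
3-channel (grayscale replicated, `channel_replicate()`), scaled to [0, 1];
preprocessing for injected backbones is the backbone's own business.
Everything is seeded: two runs with the same seed produce bit-identical
loss histories.

Transfer learning is preserved as an *injection contract*, not a
dependency: `feature_extraction` mode wraps any callable that maps images
to feature vectors and trains only the dropout+softmax head (all-but-head
frozen); `partial_retrain` takes a layered model and freezes its conv
blocks below a configurable boundary, mirroring the freeze-the-early-layers
protocol. Tests exercise the freezing contract with identity extractors;
no pretrained weights are downloaded anywhere. Class imbalance is handled
by stratification only — never resampling — because classifiers should be
evaluated on the original imbalanced distributions.

On the 6-class gallery (80 images per class, 50:10:40, threefold
augmentation, fixed seed) the scratch network reaches macro-F1 >= 0.90 on
the held-out test split within the 20-epoch budget on one CPU — the
desk-scale analogue of "maximum performance reached within a few epochs".

## Evaluation

Multi-class results are binarized one-vs-all. From 2x2 confusion counts
the package computes precision `tp/(tp+fp)`, recall `tp/(tp+fn)`,
F1 `2PR/(P+R)` and accuracy; a zero denominator yields 0 with an
`undefined` attribute flag, so empty-prediction classes cannot silently
poison macro averages. `pr_curve()` enumerates every decision threshold
(one point per unique score, ties entering together, `score >= t`
predicting positive); `average_precision()` is the uninterpolated
step-wise sum `AP = sum (R_n - R_{n-1}) P_n` with `R_0 = 0` — no 11-point
or trapezoidal variants — and each class's chance baseline is its
prevalence `y = P/(P+N)`. `metrics_report()` assembles per-class metrics
(argmax labels from the fold-ensemble mean scores), *macro* (unweighted)
averages — chosen over weighted averaging to keep minority classes
visible — and across-fold mean +/- sd of each macro metric;
`ensemble_predict()` provides the fold-mean and fold-sd score matrices.
`tidy()`, `glance()` and `autoplot()` methods expose everything as
tibbles and ggplots. ROC curves and calibration analysis are out of
scope, as is any abundance quantification.

## Problem sizes and reproducibility

The bundled experiments run at sizes a laptop CPU handles comfortably:
512 x 512 desk-scale optics (20 scenes, 75 planes each), a 480-image
gallery growing to 720 training images after augmentation, and 20 training
epochs. `scripts/acceptance.R --seed N --out results.json` re-runs the
whole battery — plane scheduling, stratified folding of the 7215-record
pool, augmentation growth, standardization, volume accounting, the
closed-loop optics experiment, classifier training and evaluation, and the
plateau schedule — from scratch under one seed and writes every measured
quantity as JSON. All randomness flows through explicit seeds; there is no
hidden global state.

## Known limitations

* The thin-mask, scalar-diffraction forward model ignores multiple
  scattering and polarization; strongly refractile or thick organisms are
  outside its validity.
* The sequential multi-plane composition is exact per object but
  approximate for the joint field of objects at different depths (correct
  to first order in object contrast).
* Global Otsu detection degrades at hologram edges under strong
  vignetting; illumination-aware detection is explicitly not implemented.
* The amplitude dip of an opaque disc is a plateau in z (the twin image
  flattens it), which is why focus selection uses Vollath F4 rather than
  amplitude extrema.
* The classifier is a desk-scale reference network; it makes no claim to
  state-of-the-art accuracy on real plankton imagery, where pretrained
  backbones injected through the extractor interface are the intended
  route.
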