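# dihm — digital in-line holographic microscopy pipeline for plankton

Plankton monitoring increasingly relies on submersible imaging instruments
that sample bulk volumes in flow. A point-source (Gabor) holographic
microscope is the simplest such design: a 405 nm laser behind a pinhole
fiber illuminates the sample volume with spherical waves, and a lensless
sensor 54 mm away records the interference of scattered and reference
light — a *hologram* that encodes the full 3-D volume in one 2048 × 2048
frame. Turning those frames into labeled plankton images requires a chain
of numerical steps, and `dihm` implements all of them as a tested R
package:

1. **Simulation** (`simulate_hologram`) — a scalar-diffraction forward
   model with exact ground truth: thin transmittance masks, angular-
   spectrum propagation under the Fresnel scaling theorem
   (`z_eff = z(L−z)/L`, magnification `M = L/z`), radial illumination
   falloff, Poisson shot noise, 8-bit quantization.
2. **Reconstruction** (`reconstruct_stack`) — background normalization to
   a contrast field and FFT back-propagation of the wavefield to a
   schedule of z-planes (300 planes for the 15 mm sample space at a 50 µm
   step), with evanescent cutoff and band-limited transfer function.
3. **Detection** (`detect_stack`) — per-plane global Otsu thresholding
   (256-bin histogram), 8-connected components, and a physical size gate
   (20–2000 µm equivalent diameter: micro- to mesoplankton).
4. **Autofocus** (`focus_pipeline`) — DBSCAN clustering of detections
   across planes by lateral centroid, then per cluster the in-focus plane
   by Vollath's F4 autocorrelation measure
   `F4 = Σ I(x,y)I(x+1,y) − Σ I(x,y)I(x+2,y)`.
5. **Dataset building** (`build_dataset`) — 128 × 128 standardization,
   threefold flip/translate augmentation, 50:10:40 train/val/test split,
   stratified 5-fold assignments, a synthetic shape gallery with a noise
   class, and the bundled 19-class abundance table
   (`holosea_taxa_counts`).
6. **Classification** (`train_fold`, `predict_proba`,
   `ensemble_predict`) — a compact conv/batch-norm/ReLU CNN with dropout
   0.3 and a softmax head, trained with Adam (lr 0.01, batch 32, 20
   epochs) under a reduce-on-plateau schedule (factor 10, min-delta 1e-3,
   patience 5); pretrained backbones plug in through a feature-extractor
   interface with feature-extraction and partial-retrain freezing modes.
7. **Evaluation** (`metrics_report`, `pr_curve`, `average_precision`) —
   one-vs-all precision/recall/F1/accuracy, precision–recall curves at
   every decision threshold, uninterpolated average precision
   `AP = Σ (R_n − R_{n−1}) P_n` against per-class chance baselines
   `y = P/(P+N)`, and fold-ensemble mean ± sd.

Results flow as tibbles through dplyr verbs, with `tidy()`, `glance()`
and `autoplot()` methods on fitted objects and reports. A thin CLI over
the same functions lives at `inst/cli/dihm.R`
(`simulate / reconstruct / detect / focus / synth / train / evaluate`).

## Worked example

Simulate a 100 µm opaque disc 2.5 mm from the point source, with shot
noise and vignetting, at the desk-scale geometry (a 512-pixel sensor with
the instrument's numerical aperture preserved — see
`?scaled_geometry`), then run the full recovery pipeline:

```r
library(dihm)

g  <- scaled_geometry(4)                      # 512 px, L = 13.5 mm, NA ≈ 0.10
ph <- scene_phantom(
  data.frame(x = 0, y = 0, z = 2500, equivalent_diameter = 100,
             transmission = 0),
  noise_seed = 1
)
h  <- simulate_hologram(ph, g, with_noise = TRUE, with_vignette = TRUE)

stack   <- reconstruct_stack(h)               # 75 planes, 1.0–4.75 mm
rois    <- detect_stack(stack)                # Otsu + size gate, all planes
objects <- focus_pipeline(rois, stack)        # DBSCAN + Vollath F4
objects[, c("z_best", "x", "y", "equivalent_diameter", "n_members")]
#> # A tibble: 1 × 5
#>   z_best       x      y equivalent_diameter n_members
#>    <dbl>   <dbl>  <dbl>               <dbl>     <int>
#> 1   2500 0.00871 0.0155                99.4        66
```

One object is recovered: depth exactly at the true 2500 µm plane (the
step is 50 µm), lateral position within a hundredth of a micrometre of
the optical axis, and equivalent diameter 99.4 µm against the true
100 µm. The disc was tracked as one DBSCAN cluster across 66 planes and
the F4 maximum picked the focus.

Training the bundled classifier on the synthetic 6-class gallery and
scoring its held-out test split:

```r
ds    <- build_dataset(synthetic_gallery(n_per_class = 80, seed = 11),
                       seed = 11)
train <- dplyr::filter(ds, split == "train")
test  <- dplyr::filter(ds, split == "test")
cfg   <- train_config(n_classes = 6, seed = 3)
fit   <- train_fold(build_model(cfg), list(x = train, y = train$label), cfg)
rep   <- metrics_report(predict_proba(fit, test), test$label)
glance(rep)
#> # A tibble: 1 × 5
#>   accuracy precision recall    f1     n
#>      <dbl>     <dbl>  <dbl> <dbl> <int>
#> 1        1         1      1     1   192
```

The six shape classes (disc, annulus, rod, chain, spiral, speckle noise)
are cleanly separable at this scale; each class's average precision also
sits at 1.0 against chance baselines of 1/6. `autoplot(rep)` draws the
per-class AP/baseline chart and `autoplot(pr_curve(...))` the
precision–recall curves.

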