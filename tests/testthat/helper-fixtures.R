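# Shared fixtures, built once per test run and cached.

.dihm_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .dihm_test_cache)) {
    assign(name, force(expr), envir = .dihm_test_cache)
  }
  get(name, envir = .dihm_test_cache)
}

# Desk-scale geometry: quarter-size instrument with the full device's
# numerical aperture (see ?scaled_geometry).
desk_geometry <- function(...) scaled_geometry(4, ...)

# Single-disc phantom scene simulated, reconstructed, detected and focused
# end-to-end; returns the focused-object table plus ground truth.
run_single_disc_scene <- function(geometry, x, y, z, diameter, seed,
                                  with_noise = TRUE, with_vignette = TRUE) {
  ph <- scene_phantom(
    data.frame(x = x, y = y, z = z, equivalent_diameter = diameter,
               transmission = 0),
    noise_seed = seed
  )
  h <- simulate_hologram(ph, geometry, with_noise = with_noise,
                         with_vignette = with_vignette)
  st <- reconstruct_stack(h)
  rois <- detect_stack(st)
  fo <- suppressMessages(focus_pipeline(rois, st))
  list(objects = fo, z_true = z, stack = st, rois = rois)
}

# Twenty random single-object scenes through the full pipeline (the
# closed-loop parameter-recovery experiment); cached across tests.
closed_loop_results <- function() {
  cached("closed_loop", {
    g <- desk_geometry()
    set.seed(42)
    res <- lapply(1:20, function(i) {
      z_true <- round(stats::runif(1, 1500, 4200))
      sc <- run_single_disc_scene(
        g,
        x = stats::runif(1, -80, 80), y = stats::runif(1, -80, 80),
        z = z_true, diameter = stats::runif(1, 60, 120), seed = 100 + i
      )
      data.frame(n_found = nrow(sc$objects),
                 z_err = if (nrow(sc$objects) >= 1) {
                   min(abs(sc$objects$z_best - z_true))
                 } else {
                   NA_real_
                 },
                 z_true = z_true)
    })
    do.call(rbind, res)
  })
}

# Synthetic 6-class gallery dataset plus a trained scratch_small model
# evaluated on the held-out test split; cached across tests.
gallery_run <- function() {
  cached("gallery_run", {
    gal <- synthetic_gallery(n_per_class = 80, seed = 11)
    ds <- build_dataset(gal, seed = 11)
    train <- ds[ds$split == "train", ]
    test <- ds[ds$split == "test", ]
    cfg <- train_config(n_classes = 6, seed = 3)
    fm <- train_fold(build_model(cfg), list(x = train, y = train$label), cfg)
    probs <- predict_proba(fm, test)
    list(dataset = ds, fold_model = fm, probs = probs,
         report = metrics_report(probs, test$label))
  })
}
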