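tiny_config <- function(...) {
  args <- utils::modifyList(list(n_classes = 3, epochs = 2, batch_size = 8,
                                 seed = 5), list(...))
  do.call(train_config, args)
}

tiny_data <- function(n_per = 6, seed = 30) {
  gal <- synthetic_gallery(classes = c("disc", "rod", "noise"),
                           n_per_class = n_per, seed = seed)
  list(x = gal, y = gal$label)
}

test_that("configuration defaults follow the training protocol", {
  cfg <- train_config()
  expect_equal(cfg$dropout, 0.3)
  expect_equal(cfg$learning_rate, 0.01)
  expect_equal(cfg$plateau_factor, 10)
  expect_equal(cfg$plateau_min_delta, 1e-3)
  expect_equal(cfg$plateau_patience, 5)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$epochs, 20L)
  expect_equal(cfg$bn_momentum, 0.9)
  expect_equal(cfg$n_classes, 19L)
  expect_error(train_config(dropout = 1), "dropout")
})

test_that("scratch model has the configured head width and seeded init", {
  cfg <- train_config(n_classes = 19)
  m <- build_model(cfg)
  dense <- m$layers[[length(m$layers)]]
  expect_equal(ncol(dense$w), 19)
  m2 <- build_model(cfg)
  expect_identical(m$layers, m2$layers)
})

test_that("mode contracts: extractor injection and freezing", {
  cfg <- train_config(mode = "feature_extraction", n_classes = 3)
  expect_error(build_model(cfg), "extractor")
  ident <- function(x) {
    d <- dim(x)
    t(matrix(x, d[1] * d[2] * d[3], d[4]))[, 1:20]
  }
  fe <- build_model(cfg, extractor = ident)
  expect_equal(trainable_parameters(fe), "dense[head]")

  pr_cfg <- train_config(mode = "partial_retrain", n_classes = 3,
                         freeze_boundary = 2)
  expect_error(build_model(pr_cfg), "dihm_model")
  base <- build_model(train_config(n_classes = 3))
  pr <- build_model(pr_cfg, extractor = base)
  tp <- trainable_parameters(pr)
  expect_false(any(grepl("block1", tp)))
  expect_true(any(grepl("block2", tp)))
  expect_true(any(grepl("head", tp)))
})

test_that("the plateau rule reduces 0.01 to 0.001 on a stalled sequence", {
  cfg <- train_config()
  losses <- c(1.0, 0.999, 0.9995, 0.9991, 0.9993, 0.9992)
  expect_equal(lr_schedule_step(losses, 0.01, cfg), 0.001)
})

test_that("steadily improving losses keep the learning rate", {
  cfg <- train_config()
  expect_equal(lr_schedule_step(seq(1, 0.8, by = -0.01), 0.01, cfg), 0.01)
})

test_that("the improvement boundary is strict, as in reduce-on-plateau", {
  cfg <- train_config(plateau_min_delta = 2^-10, plateau_patience = 2)
  # drops of exactly min_delta never reset patience (best stays put)
  exact <- c(1, 1 - 2^-10, 1 - 2^-10)
  expect_equal(lr_schedule_step(exact, 0.01, cfg), 0.001)
  # anything strictly beyond it does
  better <- c(1, 1 - 2^-9, 1 - 2 * 2^-9)
  expect_equal(lr_schedule_step(better, 0.01, cfg), 0.01)
})

test_that("training runs, learns, and records histories", {
  cfg <- tiny_config(epochs = 3)
  fm <- train_fold(build_model(cfg), tiny_data(), cfg)
  expect_length(fm$loss_history, 3)
  expect_length(fm$lr_history, 3)
  expect_true(all(diff(fm$lr_history) <= 0))
  expect_lt(fm$loss_history[3], fm$loss_history[1])
  expect_error(train_fold(build_model(cfg), list(x = list(), y = character(0)),
                          cfg), "empty")
  td <- tidy(fm)
  expect_equal(nrow(td), 3)
  expect_named(td, c("fold", "epoch", "loss", "lr"))
  expect_equal(glance(fm)$final_loss, fm$loss_history[3])
})

test_that("training is seed-reproducible", {
  cfg <- tiny_config(epochs = 2)
  f1 <- train_fold(build_model(cfg), tiny_data(), cfg)
  f2 <- train_fold(build_model(cfg), tiny_data(), cfg)
  expect_identical(f1$loss_history, f2$loss_history)
})

test_that("feature-extraction training touches only the head", {
  cfg <- train_config(mode = "feature_extraction", n_classes = 3,
                      epochs = 2, batch_size = 8, seed = 5)
  gap_extractor <- function(x) {
    d <- dim(x)
    xm <- x
    dim(xm) <- c(d[1] * d[2], d[3] * d[4])
    t(matrix(colMeans(xm), d[3], d[4]))
  }
  fe <- build_model(cfg, extractor = gap_extractor)
  fm <- train_fold(fe, tiny_data(), cfg)
  expect_length(fm$loss_history, 2)
  probs <- predict_proba(fm, tiny_data()$x)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
})

test_that("predictions are row-stochastic, pure, and near-uniform at init", {
  cfg <- tiny_config()
  m <- build_model(cfg)
  imgs <- tiny_data(n_per = 2)$x
  probs <- predict_proba(m, imgs)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  expect_true(all(probs >= 0 & probs <= 1))
  # duplicated input rows give identical score rows
  two <- imgs[c(1, 1), ]
  p2 <- predict_proba(m, two)
  expect_equal(p2[1, ], p2[2, ])
  # constant image under the symmetric small-weight init: near-uniform
  const <- list(matrix(128, 128, 128))
  pc <- predict_proba(m, tibble::tibble(image = const))
  expect_lt(max(pc) - min(pc), 0.1)
  expect_error(predict_proba(m, list(matrix(1, 64, 64))), "128")
})

test_that("fold ensembles average scores and report variance", {
  cfg <- tiny_config(epochs = 1)
  data <- tiny_data()
  fm1 <- train_fold(build_model(cfg), data, cfg, fold = 0)
  fm2 <- train_fold(build_model(tiny_config(seed = 9)), data,
                    tiny_config(seed = 9), fold = 1)
  imgs <- data$x[1:5, ]
  single <- ensemble_predict(list(fm1), imgs)
  expect_equal(single$mean, predict_proba(fm1, imgs))
  expect_true(all(single$sd == 0))
  dup <- ensemble_predict(list(fm1, fm1), imgs)
  expect_true(all(dup$sd == 0))
  ens <- ensemble_predict(list(fm1, fm2), imgs)
  expect_equal(rowSums(ens$mean), rep(1, 5), tolerance = 1e-6)
})

test_that("k-fold training yields one model per fold", {
  gal <- synthetic_gallery(classes = c("disc", "rod"), n_per_class = 8,
                           seed = 31)
  gal$fold <- rep(0:1, length.out = nrow(gal))
  cfg <- train_config(n_classes = 2, epochs = 1, batch_size = 8, seed = 2)
  fms <- train_folds(gal, cfg)
  expect_length(fms, 2)
  expect_equal(vapply(fms, `[[`, integer(1), "fold"), 0:1)
})

test_that("desk-scale classifier reaches macro-F1 >= 0.90 on held-out data", {
  run <- gallery_run()
  expect_length(run$fold_model$loss_history, 20)
  expect_gte(glance(run$report)$f1, 0.90)
})
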