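test_that("standardize_crop scales the long side and pads the canvas", {
  crop <- matrix(round(runif(300 * 100, 0, 255)), 300, 100)
  out <- standardize_crop(crop)
  expect_equal(dim(out), c(128, 128))
  # content region 128 x 43 centered; padding is the border median
  fill <- stats::median(c(crop[1, ], crop[300, ], crop[, 1], crop[, 100]))
  expect_true(all(out[, 1:42] == fill))
  expect_true(all(out[, 86:128] == fill))

  sq <- matrix(round(runif(64 * 64, 0, 255)), 64, 64)
  up <- standardize_crop(sq)
  expect_equal(dim(up), c(128, 128))
  expect_false(any(up == -1)) # fully covered, no padding sentinel needed

  same <- matrix(round(runif(128 * 128, 0, 255)), 128, 128)
  expect_identical(standardize_crop(same), same)
  expect_error(standardize_crop(matrix(numeric(0), 0, 5)), "non-empty")
})

test_that("standardize_crop is idempotent", {
  crop <- matrix(round(runif(200 * 50, 0, 255)), 200, 50)
  once <- standardize_crop(crop)
  expect_identical(standardize_crop(once), once)
})

test_that("augmentation is exactly threefold, seeded, and train/val only", {
  recs <- synthetic_gallery(classes = c("disc", "rod"), n_per_class = 5,
                            seed = 4)
  recs$split <- "train"
  aug <- augment_records(recs, seed = 7)
  expect_equal(nrow(aug), 3 * nrow(recs))
  expect_identical(augment_records(recs, seed = 7), aug)
  expect_equal(nrow(augment_records(recs[0, ], seed = 1)), 0)
  expect_equal(sum(is.na(aug$augmented_from)), nrow(recs))
  expect_setequal(stats::na.omit(aug$augmented_from), recs$id)
  # flips preserve the canvas size
  expect_true(all(vapply(aug$image, function(im) all(dim(im) == 128),
                         logical(1))))
  recs$split <- "test"
  expect_error(augment_records(recs, seed = 7), "never")
})

test_that("split honors 50:10:40 with largest-remainder rounding", {
  recs <- tibble::tibble(id = as.character(1:100), label = "a",
                         image = vector("list", 100))
  sp <- split_records(recs, seed = 1)
  expect_equal(as.vector(table(sp$split)[c("train", "val", "test")]),
               c(50, 10, 40))

  crust <- tibble::tibble(id = as.character(1:13), label = "b",
                          image = vector("list", 13))
  sp13 <- split_records(crust, seed = 1)
  expect_equal(as.vector(table(sp13$split)[c("train", "val", "test")]),
               c(7, 1, 5))

  # partition law: union of splits = input, pairwise disjoint
  both <- dplyr::bind_rows(recs, crust)
  spb <- split_records(both, seed = 2)
  expect_setequal(paste(spb$label, spb$id), paste(both$label, both$id))
  expect_true(all(table(paste(spb$label, spb$id)) == 1))

  tiny <- tibble::tibble(id = "1", label = "c", image = list(NULL))
  expect_warning(spt <- split_records(tiny, seed = 1), "train-first")
  expect_equal(spt$split, "train")
  expect_error(split_records(recs, ratios = c(60, 20, 30)), "sum to 100")
})

test_that("stratified folds balance classes and fold totals", {
  pool_counts <- holosea_taxa_counts(total = 7215)
  expect_equal(sum(pool_counts$n), 7215)
  pool <- tibble::tibble(label = rep(pool_counts$class, pool_counts$n),
                         id = as.character(seq_len(7215)))
  kf <- suppressWarnings(stratified_kfold(pool, k = 5, seed = 2))
  expect_equal(as.vector(table(kf$fold)), rep(1443, 5))
  # per-class fold counts differ by at most one
  per <- table(kf$label, kf$fold)
  expect_true(all(apply(per, 1, function(r) max(r) - min(r) <= 1)))
  # each fold's training part is the complement
  expect_equal(sum(kf$fold != 0), 5772)

  ten <- tibble::tibble(label = rep("a", 10), id = as.character(1:10))
  kf10 <- stratified_kfold(ten, k = 5, seed = 1)
  expect_equal(as.vector(table(kf10$fold)), rep(2, 5))
  expect_warning(stratified_kfold(ten[1:3, ], k = 5, seed = 1), "fewer")
})

test_that("fold proportions track pool proportions per class", {
  set.seed(20)
  pool <- tibble::tibble(
    label = sample(rep(c("a", "b", "c"), times = c(250, 100, 37))),
    id = as.character(1:387)
  )
  kf <- suppressWarnings(stratified_kfold(pool, k = 5, seed = 3))
  pool_prop <- prop.table(table(pool$label))
  fold_sizes <- table(kf$fold)
  for (f in 0:4) {
    fold_prop <- prop.table(table(kf$label[kf$fold == f]))
    for (cls in names(pool_prop)) {
      # one record of slack per class plus fold-size raggedness
      tol <- 1 / sum(pool$label == cls) + 1 / min(fold_sizes)
      expect_lt(abs(fold_prop[[cls]] - pool_prop[[cls]]), tol)
    }
  }
})

test_that("channel replication repeats the grayscale plane", {
  img <- matrix(runif(16), 4, 4)
  arr <- channel_replicate(img)
  expect_equal(dim(arr), c(4, 4, 3))
  expect_identical(arr[, , 1], img)
  expect_identical(arr[, , 2], arr[, , 3])
  expect_equal(mean(arr), mean(img))
  expect_error(channel_replicate(arr), "single-channel")
})

test_that("build_dataset never augments test records and folds the rest", {
  gal <- synthetic_gallery(classes = c("disc", "rod", "noise"),
                           n_per_class = 10, seed = 6)
  ds <- build_dataset(gal, seed = 6)
  expect_true(all(is.na(ds$augmented_from[ds$split == "test"])))
  expect_true(all(is.na(ds$fold[ds$split == "test"])))
  trainval <- ds[ds$split != "test", ]
  expect_true(all(!is.na(trainval$fold)))
  expect_equal(nrow(trainval), 3 * (nrow(gal) - sum(ds$split == "test")))
})

test_that("synthetic gallery is sized, seeded, and supports imbalance", {
  gal <- synthetic_gallery(classes = c("disc", "rod", "chain", "spiral"),
                           n_per_class = 50, seed = 5)
  expect_equal(nrow(gal), 200)
  expect_equal(as.vector(table(gal$label)), rep(50, 4))
  expect_identical(synthetic_gallery(classes = c("disc", "rod"),
                                     n_per_class = 5, seed = 5),
                   synthetic_gallery(classes = c("disc", "rod"),
                                     n_per_class = 5, seed = 5))
  imb <- synthetic_gallery(classes = c("disc", "rod"), n_per_class = 10,
                           seed = 5, class_counts = c(disc = 13, rod = 40))
  expect_equal(sum(imb$label == "disc"), 13)
  expect_equal(sum(imb$label == "rod"), 40)
  expect_error(synthetic_gallery(classes = "hexagon"), "unknown")
})

test_that("a linear probe separates disc from rod on raw pixels", {
  skip_if_not_installed("glmnet")
  gal <- synthetic_gallery(classes = c("disc", "rod"), n_per_class = 60,
                           seed = 21)
  x <- t(vapply(gal$image, as.numeric, numeric(128 * 128)))
  y <- factor(gal$label)
  set.seed(22)
  hold <- sample(nrow(x), 40)
  fit <- glmnet::glmnet(x[-hold, ], y[-hold], family = "binomial",
                        lambda = 0.01)
  pred <- predict(fit, x[hold, ], type = "class")
  expect_gte(mean(pred == as.character(y[hold])), 0.9)
})
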