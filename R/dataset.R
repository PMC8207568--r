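#' Standardize a crop to a 128 x 128 canvas
#'
#' Scales the longest side to `side` pixels with bilinear interpolation,
#' preserving the aspect ratio, and centers the result on a `side` x `side`
#' canvas padded with the median value of the crop's border ring (which
#' matches a holographic background better than zero). Already-standardized
#' images pass through unchanged, so the operation is idempotent.
#'
#' @param crop Numeric matrix (any size, both dimensions >= 1).
#' @param side Canvas side length. Default 128.
#' @return `side` x `side` matrix; integer-valued if the input was.
#' @export
standardize_crop <- function(crop, side = 128) {
  if (!is.matrix(crop) || nrow(crop) == 0 || ncol(crop) == 0) {
    stop("crop must be a non-empty matrix", call. = FALSE)
  }
  if (nrow(crop) == side && ncol(crop) == side) return(crop)
  integerish <- all(crop == round(crop))
  scale <- side / max(dim(crop))
  nr <- max(1L, as.integer(round(nrow(crop) * scale)))
  nc <- max(1L, as.integer(round(ncol(crop) * scale)))
  resized <- EBImage::resize(crop, w = nr, h = nc, filter = "bilinear")
  resized <- matrix(as.numeric(resized), nr, nc)
  fill <- border_median(crop)
  canvas <- matrix(fill, side, side)
  r0 <- (side - nr) %/% 2
  c0 <- (side - nc) %/% 2
  canvas[r0 + seq_len(nr), c0 + seq_len(nc)] <- resized
  if (integerish) canvas <- round(canvas)
  canvas
}

border_median <- function(m) {
  stats::median(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
}

#' Threefold flip/translate augmentation
#'
#' Enlarges a set of training/validation records exactly threefold: each
#' source image yields itself, a horizontal flip, and a vertical flip; the
#' two flips are each additionally translated by an independent uniform
#' shift of up to +/-10% per axis (vacated pixels take the image's border
#' median). Provenance is recorded in `augmented_from`. Test records are
#' never augmented; passing any is an error.
#'
#' @param records Manifest tibble with `id`, `label`, and an `image` list
#'   column (and optionally `split`, which must not contain `"test"`).
#' @param seed Integer seed; output is bit-identical across runs.
#' @return Manifest tibble with `3 * nrow(records)` rows.
#' @export
augment_records <- function(records, seed = 1L) {
  if ("split" %in% names(records) && any(records$split == "test")) {
    stop("test records must never be augmented", call. = FALSE)
  }
  if (nrow(records) == 0) return(records)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(records)), function(i) {
      rec <- records[i, , drop = FALSE]
      img <- rec$image[[1]]
      side <- dim(img)
      variants <- list(
        img,
        translate_image(img[, rev(seq_len(ncol(img)))],
                        sample_shift(side[1]), sample_shift(side[2])),
        translate_image(img[rev(seq_len(nrow(img))), ],
                        sample_shift(side[1]), sample_shift(side[2]))
      )
      suffix <- c("", "_h", "_v")
      res <- rec[rep(1, 3), , drop = FALSE]
      res$id <- paste0(rec$id, suffix)
      res$image <- variants
      res$augmented_from <- c(NA_character_, rec$id, rec$id)
      res
    })
    dplyr::bind_rows(out)
  })
}

sample_shift <- function(extent) {
  max_px <- floor(0.1 * extent)
  as.integer(round(stats::runif(1, -max_px, max_px)))
}

translate_image <- function(img, dr, dc) {
  fill <- border_median(img)
  out <- matrix(fill, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - dr
  src_c <- seq_len(ncol(img)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Per-class random 50:10:40 split
#'
#' Randomly partitions each class into train/validation/test splits
#' honoring the given percentage ratios with largest-remainder rounding
#' (ties broken in train, val, test order). Every class with at least 3
#' members gets at least one member per split; smaller classes are assigned
#' train-first with a warning. Splitting is performed before augmentation
#' so augmented twins never straddle splits.
#'
#' @param records Manifest tibble with a `label` column.
#' @param ratios Percentages summing to 100. Default `c(50, 10, 40)`.
#' @param seed Integer seed.
#' @return The records with a `split` column (`train`/`val`/`test`).
#' @export
split_records <- function(records, ratios = c(train = 50, val = 10, test = 40),
                          seed = 1L) {
  if (!isTRUE(all.equal(sum(ratios), 100))) {
    stop("ratios must sum to 100", call. = FALSE)
  }
  splits <- c("train", "val", "test")
  with_seed(seed, {
    records$split <- NA_character_
    for (cls in unique(records$label)) {
      idx <- sample(which(records$label == cls))
      n <- length(idx)
      if (n < 3) {
        warning(sprintf("class '%s' has %d member(s); assigned train-first",
                        cls, n))
        counts <- c(n, 0L, 0L)
      } else {
        counts <- largest_remainder(n, ratios / 100)
        while (any(counts == 0)) {
          donor <- which.max(counts)
          counts[which(counts == 0)[1]] <- 1L
          counts[donor] <- counts[donor] - 1L
        }
      }
      records$split[idx] <- rep(splits, counts)
    }
    records
  })
}

# Integer apportionment of n by fractional shares: floors plus one unit to
# the largest remainders (ties to the earliest share).
largest_remainder <- function(n, shares) {
  exact <- n * shares
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified k-fold assignment
#'
#' Assigns each record a fold in `0..k-1` such that per-class fold counts
#' differ by at most one (each fold retains the class proportions of the
#' pool) and fold totals are as equal as the arithmetic allows: per-class
#' remainders are routed to the currently least-filled folds, so a pool
#' divisible by `k` yields exactly equal folds. Fold `f`'s validation part
#' is the records with `fold == f`; its training part is the rest.
#'
#' @param records Manifest tibble (the train+validation pool) with `label`.
#' @param k Number of folds, >= 2. Default 5.
#' @param seed Integer seed.
#' @return The records with an integer `fold` column in `[0, k-1]`.
#' @export
stratified_kfold <- function(records, k = 5, seed = 1L) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  counts <- table(records$label)
  if (any(counts < k)) {
    warning("class(es) with fewer than k members: ",
            paste(names(counts)[counts < k], collapse = ", "))
  }
  with_seed(seed, {
    records$fold <- NA_integer_
    fold_totals <- integer(k)
    for (cls in names(sort(counts, decreasing = TRUE))) {
      idx <- sample(which(records$label == cls))
      n <- length(idx)
      q <- n %/% k
      r <- n %% k
      per_fold <- rep(q, k)
      if (r > 0) {
        extras <- order(fold_totals, seq_len(k))[seq_len(r)]
        per_fold[extras] <- per_fold[extras] + 1
      }
      records$fold[idx] <- rep(seq_len(k) - 1L, per_fold)
      fold_totals <- fold_totals + per_fold
    }
    records
  })
}

#' Replicate a grayscale image across three channels
#'
#' Pretrained backbones expect RGB input; the grayscale channel is repeated
#' for each color channel.
#'
#' @param image Single-channel matrix.
#' @return `nrow x ncol x 3` array with identical channels.
#' @export
channel_replicate <- function(image) {
  if (!is.matrix(image)) {
    stop("image must be a single-channel matrix", call. = FALSE)
  }
  array(image, dim = c(nrow(image), ncol(image), 3))
}

#' Build a dataset: split, augment, and fold a labeled manifest
#'
#' Applies [split_records()] (before augmentation, so augmented twins never
#' straddle train/val/test), augments the train and validation records
#' threefold with [augment_records()], and assigns [stratified_kfold()]
#' folds over the augmented train+validation pool. Test records are left
#' untouched (`fold = NA`).
#'
#' @param manifest Manifest tibble with `id`, `label`, `image`.
#' @param ratios,k,seed See [split_records()] and [stratified_kfold()].
#' @return Manifest tibble with `split`, `fold`, `augmented_from` columns.
#' @export
build_dataset <- function(manifest, ratios = c(50, 10, 40), k = 5, seed = 1L) {
  manifest <- split_records(manifest, ratios, seed = seed)
  trainval <- augment_records(manifest[manifest$split != "test", ,
                                       drop = FALSE], seed = seed + 1L)
  trainval <- stratified_kfold(trainval, k = k, seed = seed + 2L)
  test <- manifest[manifest$split == "test", , drop = FALSE]
  test$augmented_from <- NA_character_
  test$fold <- NA_integer_
  dplyr::bind_rows(trainval, test)
}

#' Synthetic plankton-like image gallery
#'
#' Generates labeled 128 x 128 8-bit images with programmatically
#' controlled morphology, standing in for plankton taxa at desk scale:
#' `disc` (circular cells), `annulus` (ring-like cells), `rod` (elongated
#' pennate shapes), `chain` (chains of small cells), `spiral` (spiral
#' colonies), and `noise` (incoherent speckle artefacts, mirroring the
#' noise class used to filter holographic artefacts). Objects are dark on a
#' bright, lightly noisy background, as reconstructed amplitude images are.
#' Class counts may be intentionally imbalanced via `class_counts`.
#'
#' @param classes Character vector of generator names (subset of the six
#'   above). Default all six.
#' @param n_per_class Images per class. Default 80.
#' @param seed Integer seed; the manifest is reproducible.
#' @param side Image side length. Default 128.
#' @param class_counts Optional named integer vector overriding
#'   `n_per_class` per class (e.g. Table-style imbalance).
#' @return Manifest tibble: `id`, `label`, `origin = "synthetic"`, `image`
#'   (list of integer matrices in `[0, 255]`).
#' @export
synthetic_gallery <- function(classes = c("disc", "annulus", "rod",
                                          "chain", "spiral", "noise"),
                              n_per_class = 80, seed = 1L, side = 128,
                              class_counts = NULL) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  known <- c("disc", "annulus", "rod", "chain", "spiral", "noise")
  bad <- setdiff(classes, known)
  if (length(bad) > 0) {
    stop("unknown shape generator(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(classes, function(cls) {
      n <- if (!is.null(class_counts) && cls %in% names(class_counts)) {
        class_counts[[cls]]
      } else {
        n_per_class
      }
      imgs <- lapply(seq_len(n), function(i) draw_shape(cls, side))
      tibble::tibble(
        id = sprintf("%s_%04d", cls, seq_len(n)),
        label = cls, origin = "synthetic", image = imgs
      )
    })
    dplyr::bind_rows(rows)
  })
}

draw_shape <- function(cls, side) {
  bg <- 200
  fg <- 60
  img <- matrix(bg + stats::rnorm(side^2, 0, 8), side, side)
  ctr <- side / 2 + stats::runif(2, -8, 8)
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  paint <- function(mask) img[mask] <<- fg + stats::rnorm(sum(mask), 0, 6)
  if (cls == "disc") {
    r <- stats::runif(1, 15, 30)
    paint((rows - ctr[1])^2 + (cols - ctr[2])^2 <= r^2)
  } else if (cls == "annulus") {
    r <- stats::runif(1, 18, 32)
    rin <- r * stats::runif(1, 0.5, 0.7)
    d2 <- (rows - ctr[1])^2 + (cols - ctr[2])^2
    paint(d2 <= r^2 & d2 >= rin^2)
  } else if (cls == "rod") {
    len <- stats::runif(1, 30, 48)
    wid <- stats::runif(1, 4, 8)
    th <- stats::runif(1, 0, pi)
    u <- (rows - ctr[1]) * cos(th) + (cols - ctr[2]) * sin(th)
    v <- -(rows - ctr[1]) * sin(th) + (cols - ctr[2]) * cos(th)
    paint((u / len)^2 + (v / wid)^2 <= 1)
  } else if (cls == "chain") {
    k <- sample(4:7, 1)
    r <- stats::runif(1, 5, 8)
    th <- stats::runif(1, 0, pi)
    span <- 2.3 * r * (k - 1) / 2
    for (j in seq_len(k)) {
      off <- -span + 2.3 * r * (j - 1)
      cy <- ctr[1] + off * cos(th)
      cx <- ctr[2] + off * sin(th)
      paint((rows - cy)^2 + (cols - cx)^2 <= r^2)
    }
  } else if (cls == "spiral") {
    theta <- seq(0, 3 * pi, length.out = 400)
    a <- stats::runif(1, 2, 4)
    b <- stats::runif(1, 2.5, 3.5)
    phase <- stats::runif(1, 0, 2 * pi)
    ry <- ctr[1] + (a + b * theta) * cos(theta + phase)
    cx <- ctr[2] + (a + b * theta) * sin(theta + phase)
    for (t in seq_along(theta)) {
      paint((rows - ry[t])^2 + (cols - cx[t])^2 <= 2.2^2)
    }
  } else if (cls == "noise") {
    blur <- gaussian_lowpass(matrix(stats::rnorm(side^2, 0, 1), side, side), 2)
    img <- img - 120 * pmax(blur, 0) * (abs(blur) > stats::quantile(abs(blur), 0.8))
  }
  matrix(as.integer(clamp(round(img), 0, 255)), side, side)
}
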