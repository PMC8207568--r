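#' Training configuration for the image classifier
#'
#' Defaults follow the training protocol used throughout the package:
#' dropout 0.3, Adam at learning rate 0.01 reduced by a factor of 10 when
#' the loss fails to improve by 1e-3 for five epochs, batch size 32, 20
#' epochs, batch-normalization momentum 0.9 (running-statistics retention),
#' and a 19-class softmax head.
#'
#' @param mode `"scratch_small"` (compact CNN defined by this package),
#'   `"feature_extraction"` (train only the head on injected features), or
#'   `"partial_retrain"` (freeze the first blocks of an injected layered
#'   model).
#' @param dropout Dropout probability in `[0, 1)`. Default 0.3.
#' @param learning_rate Initial Adam learning rate. Default 0.01.
#' @param plateau_factor Learning-rate division factor on plateau. Default 10.
#' @param plateau_min_delta Minimum loss improvement. Default 1e-3.
#' @param plateau_patience Epochs without improvement before reduction.
#'   Default 5.
#' @param batch_size Minibatch size. Default 32.
#' @param epochs Training epochs. Default 20.
#' @param bn_momentum Batch-norm running-statistics momentum. Default 0.9.
#' @param n_classes Softmax output width. Default 19.
#' @param seed Integer seed; training is reproducible given the seed.
#' @param freeze_boundary For `partial_retrain`: conv blocks with index
#'   below this are frozen. Default 2.
#' @return A `dihm_train_config` list.
#' @export
train_config <- function(mode = "scratch_small", dropout = 0.3,
                         learning_rate = 0.01, plateau_factor = 10,
                         plateau_min_delta = 1e-3, plateau_patience = 5,
                         batch_size = 32, epochs = 20, bn_momentum = 0.9,
                         n_classes = 19, seed = 1L, freeze_boundary = 2) {
  stopifnot(dropout >= 0, dropout < 1, learning_rate > 0, epochs >= 1,
            batch_size >= 1, n_classes >= 2)
  structure(list(mode = mode, dropout = dropout,
                 learning_rate = learning_rate,
                 plateau_factor = plateau_factor,
                 plateau_min_delta = plateau_min_delta,
                 plateau_patience = plateau_patience,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), bn_momentum = bn_momentum,
                 n_classes = as.integer(n_classes), seed = as.integer(seed),
                 freeze_boundary = freeze_boundary),
            class = "dihm_train_config")
}

#' Build a classifier model
#'
#' `scratch_small` builds the package's compact convolutional network: a
#' 2x average-pool stem (keeping the finest morphological detail, e.g.
#' inter-cell gaps in chains, above the Nyquist limit of the conv stack)
#' followed by three conv(3x3)-batchnorm-ReLU-maxpool blocks (8, 16, 32
#' channels), global average pooling, dropout, and a softmax head of
#' `n_classes` outputs; it expects 128 x 128 x 3 inputs in
#' 8-bit scale and normalizes them to `[0, 1]`. `feature_extraction` wraps
#' any injected feature-extractor callable (images to an N x d matrix) and
#' trains only the dropout + softmax head, preserving the extractor
#' (all-but-head frozen). `partial_retrain` takes an injected layered model
#' and freezes its conv blocks below `freeze_boundary`, retraining the
#' rest; preprocessing for injected backbones is the backbone's own
#' responsibility.
#'
#' @param config A [train_config()].
#' @param extractor For `feature_extraction`, a callable
#'   `function(images_array) -> N x d matrix`; for `partial_retrain`, a
#'   `dihm_model` to partially retrain. Required by those modes.
#' @return A `dihm_model`.
#' @export
build_model <- function(config, extractor = NULL) {
  stopifnot(inherits(config, "dihm_train_config"))
  if (config$mode == "scratch_small") {
    layers <- with_seed(config$seed, init_scratch_layers(config))
    model <- list(mode = "scratch_small", config = config, layers = layers,
                  class_levels = NULL)
  } else if (config$mode == "feature_extraction") {
    if (is.null(extractor) || !is.function(extractor)) {
      stop("feature_extraction mode requires an injected extractor callable",
           call. = FALSE)
    }
    model <- list(mode = "feature_extraction", config = config,
                  extractor = extractor, head = NULL, class_levels = NULL)
  } else if (config$mode == "partial_retrain") {
    if (is.null(extractor) || !inherits(extractor, "dihm_model")) {
      stop("partial_retrain mode requires an injected dihm_model whose ",
           "layers can be backpropagated through", call. = FALSE)
    }
    model <- extractor
    model$mode <- "partial_retrain"
    model$config <- config
    for (i in seq_along(model$layers)) {
      blk <- model$layers[[i]]$block
      if (!is.null(blk) && is.numeric(blk)) {
        model$layers[[i]]$trainable <- blk >= config$freeze_boundary
      }
    }
  } else {
    stop("unknown mode: ", config$mode, call. = FALSE)
  }
  structure(model, class = "dihm_model")
}

init_scratch_layers <- function(config) {
  conv_init <- function(cin, cout) {
    list(type = "conv",
         w = matrix(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                    9 * cin, cout),
         b = rep(0, cout), trainable = TRUE)
  }
  bn_init <- function(c_) {
    list(type = "bn", gamma = rep(1, c_), beta = rep(0, c_),
         running_mean = rep(0, c_), running_var = rep(1, c_),
         trainable = TRUE)
  }
  widths <- c(3, 8, 16, 32)
  layers <- list(list(type = "avgpool", f = 2))
  for (blk in 1:3) {
    cv <- conv_init(widths[blk], widths[blk + 1]); cv$block <- blk
    bn <- bn_init(widths[blk + 1]); bn$block <- blk
    layers <- c(layers, list(cv, bn, list(type = "relu"),
                             list(type = "maxpool")))
  }
  dense <- list(type = "dense",
                w = matrix(stats::rnorm(widths[4] * config$n_classes, 0, 0.01),
                           widths[4], config$n_classes),
                b = rep(0, config$n_classes), trainable = TRUE,
                block = "head")
  c(layers, list(list(type = "gap"),
                 list(type = "dropout", p = config$dropout),
                 dense))
}

#' Names of the trainable parameter groups of a model
#'
#' @param model A `dihm_model`.
#' @return Character vector like `"conv[block1]"`, `"dense[head]"`.
#' @export
trainable_parameters <- function(model) {
  if (model$mode == "feature_extraction") {
    return("dense[head]")
  }
  out <- character(0)
  for (l in model$layers) {
    if (!is.null(l$trainable) && l$trainable) {
      out <- c(out, sprintf("%s[block%s]", l$type, l$block %||% "?"))
    }
  }
  out
}

# Forward pass through scratch-style layers; returns logits (N x K) and,
# when training, per-layer caches for backprop.
scratch_forward <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "avgpool") {
      r <- nn_avgpool_forward(x, l$f); x <- r$out; caches[[i]] <- r
    } else if (l$type == "conv") {
      r <- nn_conv_forward(x, l$w, l$b); x <- r$out
      caches[[i]] <- if (training) r[c("m", "dims")]
    } else if (l$type == "bn") {
      r <- nn_bn_forward(x, l, training); x <- r$out
      caches[[i]] <- r[c("cache", "batch_mean", "batch_var")]
    } else if (l$type == "relu") {
      r <- nn_relu_forward(x); x <- r$out; caches[[i]] <- r["mask"]
    } else if (l$type == "maxpool") {
      r <- nn_maxpool_forward(x); x <- r$out
      caches[[i]] <- r[c("arg", "dims")]
    } else if (l$type == "gap") {
      r <- nn_gap_forward(x); x <- r$out; caches[[i]] <- r["dims"]
    } else if (l$type == "dropout") {
      r <- nn_dropout_forward(x, l$p, training); x <- r$out
      caches[[i]] <- r["mask"]
    } else if (l$type == "dense") {
      caches[[i]] <- list(input = x)
      x <- sweep(x %*% l$w, 2, l$b, `+`)
    }
  }
  list(logits = x, caches = caches)
}

scratch_backward <- function(layers, caches, dlogits) {
  grads <- vector("list", length(layers))
  g <- dlogits
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cc <- caches[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(dw = crossprod(cc$input, g), db = colSums(g))
      g <- tcrossprod(g, l$w)
    } else if (l$type == "dropout") {
      if (!is.null(cc$mask)) g <- g * cc$mask / (1 - l$p)
    } else if (l$type == "gap") {
      g <- nn_gap_backward(g, cc)
    } else if (l$type == "maxpool") {
      g <- nn_maxpool_backward(g, cc)
    } else if (l$type == "relu") {
      g <- g * cc$mask
    } else if (l$type == "bn") {
      r <- nn_bn_backward(g, cc$cache, l$gamma)
      grads[[i]] <- list(dgamma = r$dgamma, dbeta = r$dbeta)
      g <- r$dx
    } else if (l$type == "conv") {
      r <- nn_conv_backward(g, cc, l$w)
      grads[[i]] <- list(dw = r$dw, db = r$db)
      g <- r$dx
    } else if (l$type == "avgpool") {
      g <- nn_avgpool_backward(g, cc, l$f)
    }
  }
  grads
}

#' Reduce-on-plateau learning-rate step
#'
#' Replays the loss history with a best/wait counter: an epoch improves
#' when its loss drops strictly below `best - plateau_min_delta` (a drop of
#' exactly `plateau_min_delta` does not count, matching the reference
#' deep-learning implementations of reduce-on-plateau); when
#' `plateau_patience` epochs pass without improvement, the learning rate is
#' divided by `plateau_factor` and the patience counter resets. Returns the
#' rate in force after the last recorded epoch.
#'
#' @param history Numeric vector of per-epoch losses (non-empty).
#' @param current_lr Learning rate before this step.
#' @param config A [train_config()].
#' @return The (possibly reduced) learning rate.
#' @export
lr_schedule_step <- function(history, current_lr, config) {
  stopifnot(length(history) >= 1)
  fires <- plateau_fires(history, config)
  if (fires[length(fires)]) current_lr / config$plateau_factor else current_lr
}

# Logical vector: does a reduction fire after each epoch?
plateau_fires <- function(history, config) {
  best <- history[1]
  wait <- 0L
  fires <- logical(length(history))
  for (t in seq_along(history)[-1]) {
    if (history[t] < best - config$plateau_min_delta) {
      best <- history[t]
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (wait >= config$plateau_patience) {
      fires[t] <- TRUE
      wait <- 0L
    }
  }
  fires
}

# Coerce supported image inputs to an [H, W, 3, N] array.
as_image_array <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  if (is.array(images) && length(dim(images)) == 3) {
    return(array(images, dim = c(dim(images), 1)))
  }
  if (is.data.frame(images)) images <- images$image
  if (is.list(images)) {
    imgs <- lapply(images, function(im) {
      if (is.matrix(im)) channel_replicate(im) else im
    })
    d <- dim(imgs[[1]])
    return(array(unlist(imgs), dim = c(d, length(imgs))))
  }
  stop("unsupported image container", call. = FALSE)
}

#' Train one fold of the classifier
#'
#' Minimizes the cross-entropy (log loss) with the Adam optimizer at the
#' plateau-scheduled learning rate, for `config$epochs` epochs of
#' shuffled minibatches. Deterministic given `config$seed` and the fold
#' number. For `scratch_small`, pixels are scaled to `[0, 1]`
#' (8-bit inputs assumed); batch-norm running statistics are updated with
#' momentum `config$bn_momentum`.
#'
#' @param model A [build_model()] output.
#' @param fold_data List with `x` (images: array, list of matrices /
#'   3-channel arrays, or a manifest tibble with an `image` column) and `y`
#'   (labels: character or factor). Non-empty.
#' @param config A [train_config()].
#' @param fold Fold number recorded in the result. Default 0.
#' @return A `dihm_fold_model`: the trained model plus `loss_history` and
#'   `lr_history` (per epoch; `lr_history` is non-increasing).
#' @export
train_fold <- function(model, fold_data, config = model$config, fold = 0L) {
  stopifnot(inherits(model, "dihm_model"))
  y <- as.factor(fold_data$y)
  if (length(y) == 0) stop("empty fold", call. = FALSE)
  x <- as_image_array(fold_data$x)
  n <- dim(x)[4]
  stopifnot(n == length(y))
  if (nlevels(y) > config$n_classes) {
    stop("more observed classes than n_classes", call. = FALSE)
  }
  onehot_full <- diag(config$n_classes)[as.integer(y), , drop = FALSE]
  use_features <- model$mode == "feature_extraction"
  if (use_features) {
    feats <- model$extractor(x)
    if (is.null(model$head)) {
      model$head <- with_seed(config$seed, list(
        dropout = list(type = "dropout", p = config$dropout),
        dense = list(type = "dense",
                     w = matrix(stats::rnorm(ncol(feats) * config$n_classes,
                                             0, 0.01),
                                ncol(feats), config$n_classes),
                     b = rep(0, config$n_classes), trainable = TRUE,
                     block = "head")
      ))
    }
    layers <- list(model$head$dropout, model$head$dense)
  } else {
    x <- x / 255
    layers <- model$layers
  }
  adam <- list()
  step <- 0L
  lr <- config$learning_rate
  loss_hist <- numeric(0)
  lr_hist <- numeric(0)
  with_seed(config$seed + 1000L * as.integer(fold), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batch_losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- if (use_features) {
          feats[idx, , drop = FALSE]
        } else {
          x[, , , idx, drop = FALSE]
        }
        yb <- onehot_full[idx, , drop = FALSE]
        fw <- if (use_features) {
          scratch_forward_head(layers, xb, training = TRUE)
        } else {
          scratch_forward(layers, xb, training = TRUE)
        }
        probs <- nn_softmax(fw$logits)
        batch_losses <- c(batch_losses, nn_xent(probs, yb))
        dlogits <- (probs - yb) / nrow(yb)
        grads <- scratch_backward(layers, fw$caches, dlogits)
        step <- step + 1L
        for (i in seq_along(layers)) {
          l <- layers[[i]]
          if (is.null(l$trainable) || !l$trainable || is.null(grads[[i]])) next
          for (pname in param_names(l$type)) {
            gname <- paste0("d", pname)
            key <- paste0(i, ".", pname)
            if (is.null(adam[[key]])) {
              adam[[key]] <- list(m = 0 * l[[pname]], v = 0 * l[[pname]])
            }
            upd <- nn_adam_update(l[[pname]], grads[[i]][[gname]],
                                  adam[[key]], lr, step)
            l[[pname]] <- upd$param
            adam[[key]] <- upd$state
          }
          layers[[i]] <- l
        }
        # batch-norm running statistics (also for frozen-but-present BN)
        for (i in seq_along(layers)) {
          l <- layers[[i]]
          if (l$type == "bn" && !is.null(fw$caches[[i]]$batch_mean)) {
            mom <- config$bn_momentum
            l$running_mean <- mom * l$running_mean +
              (1 - mom) * fw$caches[[i]]$batch_mean
            l$running_var <- mom * l$running_var +
              (1 - mom) * fw$caches[[i]]$batch_var
            layers[[i]] <- l
          }
        }
      }
      loss_hist <- c(loss_hist, mean(batch_losses))
      lr_hist <- c(lr_hist, lr)
      lr <- lr_schedule_step(loss_hist, lr, config)
    }
  })
  if (use_features) {
    model$head$dropout <- layers[[1]]
    model$head$dense <- layers[[2]]
  } else {
    model$layers <- layers
  }
  model$class_levels <- levels(y)
  structure(list(fold = as.integer(fold), model = model,
                 loss_history = loss_hist, lr_history = lr_hist),
            class = "dihm_fold_model")
}

param_names <- function(type) {
  switch(type, conv = c("w", "b"), dense = c("w", "b"),
         bn = c("gamma", "beta"), character(0))
}

# Head-only forward for feature-extraction mode (features already N x d).
scratch_forward_head <- function(layers, feats, training) {
  caches <- vector("list", 2)
  r <- nn_dropout_forward(feats, layers[[1]]$p, training)
  caches[[1]] <- r["mask"]
  caches[[2]] <- list(input = r$out)
  logits <- sweep(r$out %*% layers[[2]]$w, 2, layers[[2]]$b, `+`)
  list(logits = logits, caches = caches)
}

#' Class-probability predictions
#'
#' Softmax probabilities for standardized 128 x 128, 3-channel images; each
#' row sums to one and the row argmax is the predicted label. Evaluation
#' mode: no dropout, batch-norm uses running statistics.
#'
#' @param model A trained `dihm_model` or `dihm_fold_model`.
#' @param images Images as accepted by [train_fold()].
#' @param batch_size Forward-pass batch size. Default 64.
#' @return N x n_classes probability matrix (columns named when the model
#'   has recorded class levels).
#' @export
predict_proba <- function(model, images, batch_size = 64) {
  if (inherits(model, "dihm_fold_model")) model <- model$model
  stopifnot(inherits(model, "dihm_model"))
  x <- as_image_array(images)
  if (model$mode == "feature_extraction") {
    if (is.null(model$head)) stop("head not initialized; train first",
                                  call. = FALSE)
    feats <- model$extractor(x)
    logits <- sweep(feats %*% model$head$dense$w, 2, model$head$dense$b, `+`)
    probs <- nn_softmax(logits)
  } else {
    if (dim(x)[1] != 128 || dim(x)[2] != 128 || dim(x)[3] != 3) {
      stop("images must be standardized 128 x 128 x 3", call. = FALSE)
    }
    x <- x / 255
    n <- dim(x)[4]
    out <- vector("list", ceiling(n / batch_size))
    for (b in seq_along(out)) {
      idx <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
      fw <- scratch_forward(model$layers, x[, , , idx, drop = FALSE],
                            training = FALSE)
      out[[b]] <- nn_softmax(fw$logits)
    }
    probs <- do.call(rbind, out)
  }
  if (!is.null(model$class_levels) &&
      length(model$class_levels) <= ncol(probs)) {
    colnames(probs) <- c(model$class_levels,
                         rep(NA, ncol(probs) - length(model$class_levels)))
  }
  probs
}

#' Fold-ensemble prediction
#'
#' Elementwise mean of the fold score matrices (still row-stochastic) and
#' the elementwise standard deviation across folds, quantifying prediction
#' variance of the ensemble of networks.
#'
#' @param fold_models Non-empty list of `dihm_fold_model`s.
#' @param images Images as accepted by [predict_proba()].
#' @return List with `mean` and `sd` matrices.
#' @export
ensemble_predict <- function(fold_models, images) {
  stopifnot(length(fold_models) >= 1)
  mats <- lapply(fold_models, predict_proba, images = images)
  ks <- vapply(mats, ncol, integer(1))
  if (length(unique(ks)) != 1) {
    stop("fold models disagree on the number of classes", call. = FALSE)
  }
  arr <- simplify2array(mats)
  m <- apply(arr, c(1, 2), mean)
  s <- if (length(mats) == 1) m * 0 else apply(arr, c(1, 2), stats::sd)
  dimnames(m) <- dimnames(mats[[1]])
  dimnames(s) <- dimnames(mats[[1]])
  list(mean = m, sd = s)
}

#' Train a model per stratified fold
#'
#' For each fold `f`, trains a fresh model on the records with
#' `fold != f` (the fold's training part). Records must carry `image`,
#' `label`, and `fold` columns.
#'
#' @param manifest Manifest tibble of the train+validation pool.
#' @param config A [train_config()].
#' @param extractor Passed to [build_model()].
#' @return List of `dihm_fold_model`s, one per fold.
#' @export
train_folds <- function(manifest, config, extractor = NULL) {
  folds <- sort(unique(manifest$fold))
  lapply(folds, function(f) {
    part <- manifest[manifest$fold != f, , drop = FALSE]
    model <- build_model(config, extractor)
    train_fold(model, list(x = part, y = part$label), config, fold = f)
  })
}

#' @export
print.dihm_model <- function(x, ...) {
  cat(sprintf("<dihm_model> mode=%s, %d classes\n",
              x$mode, x$config$n_classes))
  invisible(x)
}

#' @export
print.dihm_fold_model <- function(x, ...) {
  cat(sprintf("<dihm_fold_model> fold=%d, %d epochs, final loss %.4f\n",
              x$fold, length(x$loss_history),
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Tidy per-epoch training history
#'
#' @param x A `dihm_fold_model`.
#' @param ... Unused.
#' @return Tibble with `fold`, `epoch`, `loss`, `lr`.
#' @method tidy dihm_fold_model
#' @export
tidy.dihm_fold_model <- function(x, ...) {
  tibble::tibble(fold = x$fold, epoch = seq_along(x$loss_history),
                 loss = x$loss_history, lr = x$lr_history)
}

#' One-row training summary
#'
#' @param x A `dihm_fold_model`.
#' @param ... Unused.
#' @return Tibble with `fold`, `epochs`, `final_loss`, `final_lr`.
#' @method glance dihm_fold_model
#' @export
glance.dihm_fold_model <- function(x, ...) {
  tibble::tibble(fold = x$fold, epochs = length(x$loss_history),
                 final_loss = x$loss_history[length(x$loss_history)],
                 final_lr = x$lr_history[length(x$lr_history)])
}
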