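# Internal neural-network primitives for the compact reference CNN.
#
# Images travel as column-major arrays [H, W, C, N]; convolutions are
# realized as im2col + BLAS matrix products; all randomness goes through
# the caller-seeded base RNG so training is reproducible.

nn_pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2, d[2] + 2, d[3], d[4]))
  out[1 + seq_len(d[1]), 1 + seq_len(d[2]), , ] <- x
  out
}

# im2col for a 3x3 kernel, stride 1, pad 1: rows index (h, w, n),
# columns index (offset, channel).
nn_im2col <- function(x) {
  d <- dim(x)
  xp <- nn_pad1(x)
  m <- matrix(0, d[1] * d[2] * d[4], 9 * d[3])
  k <- 0
  for (dx in 0:2) {
    for (dy in 0:2) {
      k <- k + 1
      s <- xp[dy + seq_len(d[1]), dx + seq_len(d[2]), , , drop = FALSE]
      s <- aperm(s, c(1, 2, 4, 3))
      dim(s) <- c(d[1] * d[2] * d[4], d[3])
      m[, (k - 1) * d[3] + seq_len(d[3])] <- s
    }
  }
  m
}

nn_conv_forward <- function(x, w, b) {
  d <- dim(x)
  m <- nn_im2col(x)
  y <- m %*% w
  y <- sweep(y, 2, b, `+`)
  cout <- ncol(w)
  dim(y) <- c(d[1], d[2], d[4], cout)
  list(out = aperm(y, c(1, 2, 4, 3)), m = m, dims = d)
}

nn_conv_backward <- function(dy, cache, w) {
  d <- cache$dims
  cout <- ncol(w)
  dym <- aperm(dy, c(1, 2, 4, 3))
  dim(dym) <- c(d[1] * d[2] * d[4], cout)
  dw <- crossprod(cache$m, dym)
  db <- colSums(dym)
  dm <- tcrossprod(dym, w)
  dxp <- array(0, dim = c(d[1] + 2, d[2] + 2, d[3], d[4]))
  k <- 0
  for (dx in 0:2) {
    for (dy_ in 0:2) {
      k <- k + 1
      piece <- dm[, (k - 1) * d[3] + seq_len(d[3]), drop = FALSE]
      dim(piece) <- c(d[1], d[2], d[4], d[3])
      piece <- aperm(piece, c(1, 2, 4, 3))
      idx_r <- dy_ + seq_len(d[1])
      idx_c <- dx + seq_len(d[2])
      dxp[idx_r, idx_c, , ] <- dxp[idx_r, idx_c, , ] + piece
    }
  }
  list(dx = dxp[1 + seq_len(d[1]), 1 + seq_len(d[2]), , , drop = FALSE],
       dw = dw, db = db)
}

# Channel-wise batch normalization over (H, W, N).
nn_bn_forward <- function(x, layer, training, eps = 1e-5) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu, `-`)
    v <- colMeans(xc^2)
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
    xc <- sweep(xm, 2, mu, `-`)
  }
  ivar <- 1 / sqrt(v + eps)
  xn <- sweep(xc, 2, ivar, `*`)
  y <- sweep(sweep(xn, 2, layer$gamma, `*`), 2, layer$beta, `+`)
  dim(y) <- c(d[1], d[2], d[4], d[3])
  list(out = aperm(y, c(1, 2, 4, 3)),
       cache = list(xn = xn, ivar = ivar, dims = d),
       batch_mean = if (training) mu else NULL,
       batch_var = if (training) v else NULL)
}

nn_bn_backward <- function(dy, cache, gamma) {
  d <- cache$dims
  dym <- aperm(dy, c(1, 2, 4, 3))
  dim(dym) <- c(d[1] * d[2] * d[4], d[3])
  n <- nrow(dym)
  dgamma <- colSums(dym * cache$xn)
  dbeta <- colSums(dym)
  dxn <- sweep(dym, 2, gamma, `*`)
  # dx = ivar/n * (n*dxn - sum(dxn) - xn * sum(dxn * xn))
  t1 <- n * dxn
  t2 <- matrix(colSums(dxn), n, ncol(dxn), byrow = TRUE)
  t3 <- cache$xn * matrix(colSums(dxn * cache$xn), n, ncol(dxn), byrow = TRUE)
  dx <- sweep(t1 - t2 - t3, 2, cache$ivar / n, `*`)
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dx, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

nn_relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)

nn_maxpool_forward <- function(x) {
  d <- dim(x)
  ro <- seq(1, d[1], by = 2)
  co <- seq(1, d[2], by = 2)
  cand <- list(
    x[ro, co, , , drop = FALSE], x[ro + 1, co, , , drop = FALSE],
    x[ro, co + 1, , , drop = FALSE], x[ro + 1, co + 1, , , drop = FALSE]
  )
  best <- cand[[1]]
  arg <- array(1L, dim = dim(best))
  for (k in 2:4) {
    upd <- cand[[k]] > best
    best[upd] <- cand[[k]][upd]
    arg[upd] <- k
  }
  list(out = best, arg = arg, dims = d)
}

nn_maxpool_backward <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, dim = d)
  ro <- seq(1, d[1], by = 2)
  co <- seq(1, d[2], by = 2)
  offs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (k in 1:4) {
    sel <- dy * (cache$arg == k)
    dx[ro + offs[[k]][1], co + offs[[k]][2], , ] <-
      dx[ro + offs[[k]][1], co + offs[[k]][2], , ] + sel
  }
  dx
}

nn_avgpool_forward <- function(x, f) {
  d <- dim(x)
  y <- x
  dim(y) <- c(f, d[1] / f, d[2], d[3], d[4])
  y <- colMeans(y)
  y <- aperm(y, c(2, 1, 3, 4))
  dim(y) <- c(f, d[2] / f, d[1] / f, d[3], d[4])
  y <- colMeans(y)
  list(out = aperm(y, c(2, 1, 3, 4)), dims = d)
}

nn_avgpool_backward <- function(dy, cache, f) {
  d <- cache$dims
  dx <- array(0, dim = d)
  for (i in seq_len(f)) {
    for (j in seq_len(f)) {
      dx[seq(i, d[1], by = f), seq(j, d[2], by = f), , ] <- dy / f^2
    }
  }
  dx
}

nn_gap_forward <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  feat <- matrix(colMeans(xm), d[3], d[4])
  list(out = t(feat), dims = d) # N x C
}

nn_gap_backward <- function(dfeat, cache) {
  d <- cache$dims
  g <- t(dfeat) / (d[1] * d[2]) # C x N
  x <- array(0, dim = d)
  for (n in seq_len(d[4])) {
    for (c in seq_len(d[3])) x[, , c, n] <- g[c, n]
  }
  x
}

nn_dropout_forward <- function(f, p, training) {
  if (!training || p <= 0) return(list(out = f, mask = NULL))
  mask <- matrix(stats::runif(length(f)) >= p, nrow(f), ncol(f))
  list(out = f * mask / (1 - p), mask = mask, p = p)
}

nn_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

nn_xent <- function(probs, onehot) {
  -mean(log(pmax(rowSums(probs * onehot), 1e-12)))
}

nn_adam_update <- function(param, grad, state, lr, t,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}
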