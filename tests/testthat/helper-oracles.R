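# Independent brute-force oracles used to cross-check the implementation.

# Otsu: exhaustive scan over the 255 split points of a 256-bin histogram,
# computing the between-class variance from the binned pixel values.
oracle_otsu <- function(image) {
  x <- as.numeric(image)
  lo <- min(x); hi <- max(x)
  width <- (hi - lo) / 256
  bin <- pmin(floor((x - lo) / width) + 1, 256)
  centers <- lo + (bin - 0.5) * width
  best_s <- NA
  best_var <- -Inf
  for (s in 1:255) {
    in0 <- bin <= s
    w0 <- mean(in0); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    sb <- w0 * w1 * (mean(centers[in0]) - mean(centers[!in0]))^2
    if (sb > best_var + 1e-12) {
      best_var <- sb
      best_s <- s
    }
  }
  lo + best_s * width
}

# DBSCAN: O(n^2) distance matrix; clusters = graph components of the
# core-point adjacency (igraph); border points join the nearest core's
# cluster. Same definition as the package, entirely different machinery.
oracle_dbscan <- function(x, y, eps, min_samples) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  nbr <- d <= eps
  core <- rowSums(nbr) >= min_samples
  labels <- integer(n)
  if (any(core)) {
    adj <- nbr[core, core, drop = FALSE]
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                              diag = FALSE)
    comp <- igraph::components(gr)$membership
    labels[core] <- comp
    for (i in which(!core)) {
      cand <- which(nbr[i, ] & core)
      if (length(cand) > 0) {
        labels[i] <- labels[cand[which.min(d[i, cand])]]
      }
    }
  }
  labels
}

# Canonical form of a clustering: list of member-index sets, plus noise set.
partition_sets <- function(labels) {
  ids <- setdiff(unique(labels), 0)
  clusters <- lapply(ids, function(id) sort(which(labels == id)))
  list(clusters = unname(clusters[order(vapply(clusters, min, integer(1)))]),
       noise = sort(which(labels == 0)))
}

# Angular-spectrum propagation via explicit O(N^4) DFT sums with the
# scalar transfer function written out pointwise.
oracle_propagate_dft <- function(field, distance, wavelength, pitch) {
  n <- nrow(field)
  idx <- seq_len(n) - 1
  spec <- matrix(0 + 0i, n, n)
  for (p in idx) {
    for (q in idx) {
      s <- 0 + 0i
      for (a in idx) {
        for (b in idx) {
          s <- s + field[a + 1, b + 1] *
            exp(-2i * pi * (p * a + q * b) / n)
        }
      }
      spec[p + 1, q + 1] <- s
    }
  }
  freq <- function(k) (if (k > n / 2) k - n else k) / (n * pitch)
  out <- matrix(0 + 0i, n, n)
  for (a in idx) {
    for (b in idx) {
      s <- 0 + 0i
      for (p in idx) {
        for (q in idx) {
          arg <- 1 / wavelength^2 - freq(p)^2 - freq(q)^2
          h <- if (arg > 0) exp(2i * pi * distance * sqrt(arg)) else 0
          s <- s + spec[p + 1, q + 1] * h *
            exp(2i * pi * (p * a + q * b) / n)
        }
      }
      out[a + 1, b + 1] <- s / n^2
    }
  }
  out
}

# Precision-recall by explicit per-threshold confusion counting.
oracle_pr <- function(scores, truth) {
  ts <- sort(unique(scores), decreasing = TRUE)
  do.call(rbind, lapply(ts, function(t) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred == 1 & truth == 1)
    data.frame(threshold = t, precision = tp / sum(pred == 1),
               recall = tp / sum(truth == 1))
  }))
}

# Average precision by literal term-by-term expansion with R_0 = 0.
oracle_ap <- function(precision, recall) {
  r_prev <- 0
  total <- 0
  for (i in seq_along(precision)) {
    total <- total + (recall[i] - r_prev) * precision[i]
    r_prev <- recall[i]
  }
  total
}
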