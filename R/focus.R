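#' Cluster ROIs across z-planes with DBSCAN
#'
#' The same physical object is detected on several consecutive planes at
#' nearly the same lateral position, so detections are grouped by DBSCAN
#' over their 2-D lateral centroids (x, y in um); z is excluded from the
#' feature space. Core points have at least `min_samples` neighbours
#' (including themselves) within `eps`; clusters are the connected
#' components of the core-point graph; non-core points within `eps` of a
#' core point join the cluster of the nearest such core (border points);
#' the rest are noise and are returned separately, never dropped silently.
#' The partition is invariant to input order.
#'
#' @param rois ROI tibble (needs `x` and `y` columns).
#' @param eps Neighbourhood radius (um). Default 10.
#' @param min_samples Minimum neighbourhood size for a core point. Default 2.
#' @return A list with `clusters` (the ROI tibble restricted to clustered
#'   rows, with a `cluster_id` column) and `noise` (the unclustered rows).
#' @export
cluster_rois <- function(rois, eps = 10, min_samples = 2) {
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  if (min_samples < 1) stop("min_samples must be >= 1", call. = FALSE)
  labels <- dbscan_labels(rois$x, rois$y, eps, min_samples)
  clustered <- rois[labels > 0, , drop = FALSE]
  clustered$cluster_id <- labels[labels > 0]
  list(clusters = tibble::as_tibble(clustered),
       noise = tibble::as_tibble(rois[labels == 0, , drop = FALSE]))
}

# DBSCAN over 2-D points; returns integer labels (0 = noise). Cluster ids
# are renumbered by each cluster's smallest (x, y) lexicographic member so
# the labeling itself is order-invariant.
dbscan_labels <- function(x, y, eps, min_samples) {
  n <- length(x)
  if (n == 0) return(integer(0))
  d2 <- outer(x, x, `-`)^2 + outer(y, y, `-`)^2
  nbr <- d2 <= eps^2 # includes self
  core <- rowSums(nbr) >= min_samples
  labels <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    labels[i] <- cid
    while (length(queue) > 0) {
      j <- queue[[1]]
      queue <- queue[-1]
      reach <- which(nbr[j, ] & core & labels == 0L)
      labels[reach] <- cid
      queue <- c(queue, reach)
    }
  }
  # border points: nearest core within eps decides the cluster
  for (i in which(!core)) {
    cand <- which(nbr[i, ] & core)
    if (length(cand) > 0) {
      best <- cand[order(d2[i, cand], labels[cand], cand)][1]
      labels[i] <- labels[best]
    }
  }
  renumber_by_position(labels, x, y)
}

renumber_by_position <- function(labels, x, y) {
  ids <- setdiff(unique(labels), 0L)
  if (length(ids) == 0) return(labels)
  key <- vapply(ids, function(id) {
    m <- labels == id
    o <- order(x[m], y[m])[1]
    c(x[m][o], y[m][o])
  }, numeric(2))
  new_ids <- order(key[1, ], key[2, ])
  remap <- integer(max(ids))
  remap[ids[new_ids]] <- seq_along(ids)
  out <- labels
  out[labels > 0] <- remap[labels[labels > 0]]
  out
}

#' Vollath F4 autocorrelation focus measure
#'
#' `F4 = sum I(x, y) * I(x+1, y) - sum I(x, y) * I(x+2, y)`, with both sums
#' taken over the common support of the two shift terms (columns
#' `1..W-2`), so a constant image scores exactly 0. The shift runs along x
#' (image rows' horizontal direction, i.e. across columns), the original
#' 1-D formulation; crops are near-square so anisotropy is negligible. The
#' measure is maximal at best focus and scales quadratically with image
#' intensity. `convention = "naive"` restores the textbook ranges, where
#' the first sum has one extra column.
#'
#' @param crop Numeric matrix, at least 3 columns wide.
#' @param convention `"common"` (default) or `"naive"` summation support.
#' @return Scalar focus score.
#' @export
vollath_f4 <- function(crop, convention = c("common", "naive")) {
  convention <- match.arg(convention)
  if (!is.matrix(crop) || ncol(crop) < 3) {
    stop("crop must be a matrix at least 3 columns wide", call. = FALSE)
  }
  w <- ncol(crop)
  s2 <- sum(crop[, 1:(w - 2)] * crop[, 3:w])
  s1 <- if (convention == "common") {
    sum(crop[, 1:(w - 2)] * crop[, 2:(w - 1)])
  } else {
    sum(crop[, 1:(w - 1)] * crop[, 2:w])
  }
  s1 - s2
}

# Padded-bbox crop of a ROI from its own plane, clipped to plane bounds.
# An explicit (row0, col0, row1, col1) window overrides the ROI's own bbox,
# allowing a common-size window across cluster members.
crop_roi <- function(plane, roi, pad_px = 8, window = NULL) {
  amp <- plane$amplitude
  box <- window %||% c(roi$row0, roi$col0, roi$row1, roi$col1)
  r <- (box[1] + 1 - pad_px):(box[3] + pad_px)
  c <- (box[2] + 1 - pad_px):(box[4] + pad_px)
  amp[r[r >= 1 & r <= nrow(amp)], c[c >= 1 & c <= ncol(amp)], drop = FALSE]
}

#' Select the in-focus plane within one ROI cluster
#'
#' Scores each member's crop (taken from its own plane) with
#' [vollath_f4()] and keeps the member with the highest score — the
#' in-focus view of the object; the rest of the cluster is discarded.
#' Exact ties go to the lowest z.
#'
#' F4 is an unnormalized sum, so scores are only comparable over windows of
#' equal size: members are therefore scored through a common window — the
#' padded bounding box of the cluster's most compact member (detections
#' dilate with defocus, so the smallest bbox tracks the object's true
#' footprint), re-centered on each member's own bounding-box center at its
#' plane. This is the classic fixed-window z-stack autofocus. The winning
#' member's crop through that window is returned.
#'
#' @param members ROI tibble: the members of one cluster.
#' @param stack The `dihm_stack` the ROIs were detected in.
#' @param pad_px Padding around the bounding box before scoring and export
#'   (default 8); fringe context aids focus scoring.
#' @return One-row tibble: `cluster_id` (if present), `z_best`, `f4_score`,
#'   `x`, `y`, `equivalent_diameter`, `n_members`, and the winning `crop`
#'   (list column).
#' @export
select_focus <- function(members, stack, pad_px = 8) {
  stopifnot(inherits(stack, "dihm_stack"), nrow(members) > 0)
  members <- members[order(members$z), , drop = FALSE]
  ref <- which.min(members$area_px)
  half_r <- ceiling((members$row1[ref] - members$row0[ref]) / 2)
  half_c <- ceiling((members$col1[ref] - members$col0[ref]) / 2)
  crops <- lapply(seq_len(nrow(members)), function(i) {
    cr <- floor((members$row0[i] + members$row1[i]) / 2)
    cc <- floor((members$col0[i] + members$col1[i]) / 2)
    crop_roi(stack$planes[[members$plane_index[i]]], members[i, ], pad_px,
             window = c(cr - half_r, cc - half_c, cr + half_r, cc + half_c))
  })
  ok <- vapply(crops, function(cr) ncol(cr) >= 3, logical(1))
  if (!any(ok)) {
    stop("all member crops are degenerate (narrower than 3 columns)",
         call. = FALSE)
  }
  scores <- rep(-Inf, length(crops))
  scores[ok] <- vapply(crops[ok], vollath_f4, numeric(1))
  best <- which.max(scores) # members sorted by z, so ties pick lowest z
  tibble::tibble(
    cluster_id = if ("cluster_id" %in% names(members)) {
      members$cluster_id[best]
    } else {
      NA_integer_
    },
    z_best = members$z[best],
    f4_score = scores[best],
    x = members$x[best],
    y = members$y[best],
    equivalent_diameter = members$equivalent_diameter[best],
    n_members = nrow(members),
    crop = list(crops[[best]])
  )
}

#' Cluster detections and select one in-focus object per cluster
#'
#' [cluster_rois()] followed by [select_focus()] on every cluster: one
#' focused object per cluster; noise ROIs are excluded and reported via a
#' message.
#'
#' @inheritParams cluster_rois
#' @inheritParams select_focus
#' @return Tibble of focused objects (one row per cluster) with a `crop`
#'   list column.
#' @export
focus_pipeline <- function(rois, stack, eps = 10, min_samples = 2,
                           pad_px = 8) {
  cl <- cluster_rois(rois, eps, min_samples)
  if (nrow(cl$noise) > 0) {
    message(nrow(cl$noise), " ROI(s) classified as noise and excluded")
  }
  if (nrow(cl$clusters) == 0) {
    return(tibble::tibble(
      cluster_id = integer(), z_best = numeric(), f4_score = numeric(),
      x = numeric(), y = numeric(), equivalent_diameter = numeric(),
      n_members = integer(), crop = list()
    ))
  }
  cl$clusters |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::group_map(~ select_focus(.x |>
                                      dplyr::mutate(cluster_id = .y$cluster_id),
                                    stack, pad_px)) |>
    dplyr::bind_rows()
}
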