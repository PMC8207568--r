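#' Otsu threshold over a 256-bin histogram
#'
#' Global threshold maximizing the between-class variance of a 256-bin
#' histogram spanning the image's `[min, max]` range. Ties are broken toward
#' the lowest threshold; the result is deterministic.
#'
#' @param image Numeric matrix or vector with at least two distinct values.
#' @return Scalar threshold strictly inside `(min, max)`.
#' @export
otsu_threshold <- function(image) {
  x <- as.numeric(image)
  lo <- min(x); hi <- max(x)
  if (!(hi > lo)) {
    stop("degenerate input: image has a single value", call. = FALSE)
  }
  nbin <- 256L
  width <- (hi - lo) / nbin
  bin <- pmin(floor((x - lo) / width) + 1L, nbin)
  counts <- tabulate(bin, nbins = nbin)
  p <- counts / length(x)
  centers <- lo + (seq_len(nbin) - 0.5) * width
  w0 <- cumsum(p)[-nbin]
  m0 <- cumsum(p * centers)[-nbin]
  mtot <- sum(p * centers)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbin - 1L)
  sigma_b[valid] <- (mtot * w0[valid] - m0[valid])^2 /
    (w0[valid] * w1[valid])
  s <- which.max(sigma_b) # lowest index on ties
  lo + s * width
}

#' Segment one reconstructed plane into labeled components
#'
#' Thresholds the plane's amplitude with [otsu_threshold()] (dark polarity:
#' foreground below the threshold, matching absorbing plankton on a bright
#' background), labels 8-connected components, and discards components
#' smaller than `min_area` pixels (salt-noise suppression).
#'
#' A globally adaptive threshold is only meaningful when the foreground is
#' a minority of the field; on planes where every object is far out of
#' focus the amplitude histogram is unimodal ripple and Otsu floods a large
#' fraction of the grid. Such planes are treated as carrying no detections:
#' if the thresholded foreground exceeds `max_fill` of the plane, an empty
#' mask is returned with a warning.
#'
#' @param plane A `dihm_plane`.
#' @param polarity `"dark"` (default) or `"bright"` foreground.
#' @param min_area Minimum component area in pixels (default 4).
#' @param max_fill Maximum foreground fraction for a usable threshold
#'   (default 0.2).
#' @return Integer label matrix (0 = background, components labeled 1..K).
#'   A constant (degenerate) plane yields an empty mask with a warning.
#' @export
segment_plane <- function(plane, polarity = c("dark", "bright"),
                          min_area = 4, max_fill = 0.2) {
  stopifnot(inherits(plane, "dihm_plane"))
  polarity <- match.arg(polarity)
  amp <- plane$amplitude
  if (max(amp) == min(amp)) {
    warning("degenerate plane: constant amplitude, empty mask")
    return(matrix(0L, nrow(amp), ncol(amp)))
  }
  thr <- otsu_threshold(amp)
  fg <- if (polarity == "dark") amp < thr else amp > thr
  if (mean(fg) > max_fill) {
    warning("foreground exceeds max_fill: no separable objects on plane")
    return(matrix(0L, nrow(amp), ncol(amp)))
  }
  lab <- label_components_8(fg)
  if (min_area > 1 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= min_area)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  lab
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a union-find pass over the two diagonal
# adjacency directions.
label_components_8 <- function(fg) {
  lab <- EBImage::bwlabel(fg)
  lab <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  k <- max(lab)
  if (k <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' Extract regions of interest from a labeled plane
#'
#' One ROI per label, with pixel measurements converted to physical units
#' via the plane's object-plane pixel size. The equivalent diameter of a
#' component of `area_px` pixels is
#' `object_pixel_size * 2 * sqrt(area_px / pi)`. Centroids are reported as
#' (x, y) = (column, row) pixel centroids relative to the optical axis (the
#' grid center), scaled by the object pixel size — axis-centered physical
#' coordinates are stable across planes for the same object, which is what
#' cross-plane clustering relies on. Bounding boxes are half-open 0-based
#' pixel intervals.
#'
#' @param mask Integer label matrix from [segment_plane()].
#' @param plane The `dihm_plane` the mask was computed from.
#' @param plane_index Optional integer stored with each ROI.
#' @return A tibble with one row per ROI: `plane_index`, `z`, `x`, `y`,
#'   `row0`, `col0`, `row1`, `col1`, `area_px`, `equivalent_diameter`,
#'   `mean_amplitude`.
#' @export
extract_rois <- function(mask, plane, plane_index = NA_integer_) {
  stopifnot(inherits(plane, "dihm_plane"),
            all(dim(mask) == dim(plane$amplitude)))
  empty <- tibble::tibble(
    plane_index = integer(), z = numeric(), x = numeric(), y = numeric(),
    row0 = integer(), col0 = integer(), row1 = integer(), col1 = integer(),
    area_px = integer(), equivalent_diameter = numeric(),
    mean_amplitude = numeric()
  )
  if (max(mask) == 0) return(empty)
  px <- which(mask > 0)
  lab <- mask[px]
  rows <- ((px - 1) %% nrow(mask)) + 1
  cols <- ((px - 1) %/% nrow(mask)) + 1
  amp <- plane$amplitude[px]
  ops <- plane$object_pixel_size
  agg <- function(v, f) as.numeric(tapply(v, lab, f))
  area <- as.integer(tabulate(lab, nbins = max(lab)))[sort(unique(lab))]
  tibble::tibble(
    plane_index = as.integer(plane_index),
    z = plane$z,
    x = (agg(cols, mean) - (ncol(mask) + 1) / 2) * ops,
    y = (agg(rows, mean) - (nrow(mask) + 1) / 2) * ops,
    row0 = as.integer(agg(rows, min) - 1),
    col0 = as.integer(agg(cols, min) - 1),
    row1 = as.integer(agg(rows, max)),
    col1 = as.integer(agg(cols, max)),
    area_px = area,
    equivalent_diameter = ops * 2 * sqrt(area / pi),
    mean_amplitude = agg(amp, mean)
  )
}

#' Filter ROIs by physical size
#'
#' Keeps ROIs whose equivalent diameter lies inside the closed interval
#' `[min_diameter, max_diameter]`; the default 20-2000 um gate spans the
#' micro-mesoplankton size range (two orders of magnitude). Order is
#' preserved and the filter is idempotent.
#'
#' @param rois ROI tibble from [extract_rois()] / [detect_stack()].
#' @param min_diameter,max_diameter Gate bounds (um), `0 < min < max`.
#' @return Filtered ROI tibble.
#' @export
size_filter <- function(rois, min_diameter = 20, max_diameter = 2000) {
  if (!(min_diameter > 0 && min_diameter < max_diameter)) {
    stop("size gate requires 0 < min_diameter < max_diameter", call. = FALSE)
  }
  dplyr::filter(rois,
                .data$equivalent_diameter >= min_diameter,
                .data$equivalent_diameter <= max_diameter)
}

#' Detect gated ROIs on every plane of a reconstruction stack
#'
#' Per-plane [segment_plane()] + [extract_rois()] + [size_filter()],
#' concatenated with each ROI carrying its plane index and z-distance.
#' Planes are processed independently, so the result does not depend on
#' processing order.
#'
#' @param stack A `dihm_stack`.
#' @inheritParams size_filter
#' @inheritParams segment_plane
#' @param max_fill Passed to [segment_plane()].
#' @return ROI tibble across all planes.
#' @export
detect_stack <- function(stack, min_diameter = 20, max_diameter = 2000,
                         polarity = "dark", min_area = 4, max_fill = 0.2) {
  stopifnot(inherits(stack, "dihm_stack"))
  res <- purrr::imap(stack$planes, function(plane, i) {
    mask <- suppressWarnings(segment_plane(plane, polarity, min_area,
                                           max_fill))
    size_filter(extract_rois(mask, plane, plane_index = i),
                min_diameter, max_diameter)
  })
  dplyr::bind_rows(res)
}
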