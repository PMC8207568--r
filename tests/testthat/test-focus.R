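roi_row <- function(x, y, z = 1000, plane_index = 1L) {
  tibble::tibble(plane_index = plane_index, z = z, x = x, y = y,
                 row0 = 0L, col0 = 0L, row1 = 8L, col1 = 8L,
                 area_px = 64L, equivalent_diameter = 16,
                 mean_amplitude = 0.5)
}

test_that("coincident ROIs cluster; isolated ROIs are noise", {
  rois <- dplyr::bind_rows(roi_row(5, 5, 1000), roi_row(5, 5, 1050),
                           roi_row(5, 5, 1100))
  cl <- cluster_rois(rois, eps = 10, min_samples = 2)
  expect_equal(nrow(cl$clusters), 3)
  expect_equal(unique(cl$clusters$cluster_id), 1L)
  expect_equal(nrow(cl$noise), 0)

  far <- dplyr::bind_rows(roi_row(0, 0), roi_row(500, 0))
  cl2 <- cluster_rois(far, eps = 10, min_samples = 2)
  expect_equal(nrow(cl2$clusters), 0)
  expect_equal(nrow(cl2$noise), 2)
})

test_that("DBSCAN matches the O(n^2) reachability oracle on random points", {
  skip_if_not_installed("igraph")
  set.seed(12)
  for (case in 1:4) {
    n <- 40
    x <- runif(n, 0, 100)
    y <- runif(n, 0, 100)
    eps <- c(8, 12, 20, 5)[case]
    ms <- c(2, 3, 4, 2)[case]
    mine <- dihm:::dbscan_labels(x, y, eps, ms)
    ref <- oracle_dbscan(x, y, eps, ms)
    expect_equal(partition_sets(mine), partition_sets(ref))
  }
})

test_that("DBSCAN partition is invariant to input order", {
  set.seed(13)
  n <- 30
  rois <- roi_row(runif(n, 0, 60), runif(n, 0, 60))
  rois$id <- seq_len(n)
  cl1 <- cluster_rois(rois, eps = 9, min_samples = 2)
  perm <- sample(n)
  cl2 <- cluster_rois(rois[perm, ], eps = 9, min_samples = 2)
  sets <- function(cl) {
    parts <- split(cl$clusters$id, cl$clusters$cluster_id)
    list(clusters = unname(lapply(parts, sort))[
           order(vapply(lapply(parts, sort), min, numeric(1)))],
         noise = sort(cl$noise$id))
  }
  expect_equal(sets(cl1), sets(cl2))
})

test_that("vollath F4 follows the two-term autocorrelation formula", {
  expect_equal(vollath_f4(matrix(5, 7, 9)), 0)
  m <- matrix(rep(1:3, each = 3), 3, 3) # every row is (1, 2, 3)
  # brute-force expansion over the common support (column 1 only)
  expect_equal(vollath_f4(m), sum(m[, 1] * m[, 2]) - sum(m[, 1] * m[, 3]))
  expect_equal(vollath_f4(m), -3)
  expect_error(vollath_f4(matrix(1, 5, 2)), "3 columns")
})

test_that("F4 prefers the sharp version of an edge crop", {
  side <- 33
  d2 <- outer((1:side - 17)^2, (1:side - 17)^2, `+`)
  sharp <- ifelse(d2 <= 100, 0.1, 1)
  blur <- EBImage::filter2(sharp, matrix(1 / 9, 3, 3))
  blur <- matrix(as.numeric(blur), side, side)
  expect_gte(vollath_f4(sharp), vollath_f4(blur))
})

test_that("F4 scales quadratically and ignores uniform surroundings", {
  set.seed(14)
  crop <- matrix(runif(11 * 11), 11, 11)
  expect_equal(vollath_f4(3 * crop), 9 * vollath_f4(crop))
  # translating interior content inside a constant field leaves F4 unchanged
  canvas1 <- matrix(1, 31, 31); canvas1[5:15, 5:15] <- crop
  canvas2 <- matrix(1, 31, 31); canvas2[15:25, 13:23] <- crop
  expect_equal(vollath_f4(canvas1), vollath_f4(canvas2), tolerance = 1e-12)
})

test_that("focus selection takes the argmax member, ties to lowest z", {
  g <- scaled_geometry(4, sensor_pixels = 64)
  amp <- matrix(1, 64, 64)
  amp[20:30, 20:30] <- 0.2
  st <- structure(list(planes = list(dihm:::new_plane(1000, amp, 1),
                                     dihm:::new_plane(1050, amp, 1)),
                       geometry = g, source = "test"),
                  class = "dihm_stack")
  members <- dplyr::bind_rows(
    tibble::tibble(plane_index = 1L, z = 1000, x = 0, y = 0, row0 = 19L,
                   col0 = 19L, row1 = 30L, col1 = 30L, area_px = 121L,
                   equivalent_diameter = 12, mean_amplitude = 0.2),
    tibble::tibble(plane_index = 2L, z = 1050, x = 0, y = 0, row0 = 19L,
                   col0 = 19L, row1 = 30L, col1 = 30L, area_px = 121L,
                   equivalent_diameter = 12, mean_amplitude = 0.2)
  )
  sel <- select_focus(members, st)
  expect_equal(sel$z_best, 1000) # bit-identical crops: lowest z wins
  single <- select_focus(members[2, ], st)
  expect_equal(single$z_best, 1050)
  expect_equal(single$f4_score,
               vollath_f4(sel$crop[[1]]))
})

test_that("focus pipeline returns one object per cluster", {
  g <- scaled_geometry(4)
  ph3 <- scene_phantom(data.frame(x = c(-150, 0, 150), y = c(-100, 120, 0),
                                  z = c(1800, 2500, 3400),
                                  equivalent_diameter = c(60, 90, 70),
                                  transmission = 0), noise_seed = 9)
  h3 <- simulate_hologram(ph3, g, with_noise = TRUE)
  st3 <- reconstruct_stack(h3)
  rois <- detect_stack(st3)
  fo <- suppressMessages(focus_pipeline(rois, st3))
  expect_equal(nrow(fo), 3)
  cl <- cluster_rois(rois)
  expect_equal(nrow(fo), length(unique(cl$clusters$cluster_id)))
  # ground-truth positions recovered
  got <- fo[order(fo$z_best), ]
  expect_equal(got$z_best, c(1800, 2500, 3400), tolerance = 0.05)
  expect_equal(got$x, c(-150, 0, 150), tolerance = 0.1)
  # empty input
  expect_equal(nrow(focus_pipeline(rois[0, ], st3)), 0)
})

test_that("closed-loop z recovery stays within one step (median)", {
  res <- closed_loop_results()
  expect_true(all(res$n_found == 1))
  expect_lte(stats::median(res$z_err), 50)
})
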