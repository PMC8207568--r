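test_that("one-vs-all binarization partitions the label set", {
  expect_equal(binarize_labels(c("A", "B", "A"), "A"), c(1L, 0L, 1L))
  expect_warning(z <- binarize_labels(c("A", "B"), "C",
                                      levels = c("A", "B", "C")),
                 "absent")
  expect_equal(z, c(0L, 0L))
  expect_error(binarize_labels(c("A", "B"), "Z"), "unknown")
  labs <- sample(c("A", "B", "C"), 20, replace = TRUE)
  total <- Reduce(`+`, lapply(c("A", "B", "C"),
                              function(cl) binarize_labels(labs, cl,
                                                           levels = c("A", "B", "C"))))
  expect_equal(total, rep(1L, 20))
})

test_that("confusion counts enumerate the 2x2 table", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cc), list(tp = 1L, fp = 1L, fn = 1L, tn = 1L),
               ignore_attr = TRUE)
  eq <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(eq$fp + eq$fn, 0)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 4)
  expect_error(confusion_counts(c(1, 0), c(1)), "equal length")
})

test_that("threshold metrics follow their defining formulas", {
  cc <- confusion_counts(c(rep(1, 10), rep(0, 10)),
                         c(rep(1, 9), 0, rep(0, 5), rep(1, 5)))
  expect_equal(precision_score(cc), 0.9)
  p <- 1; r <- 0.5
  expect_equal(2 * p * r / (p + r), 2 / 3)
  cc2 <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 1, 0))
  expect_equal(f1_score(cc2),
               2 * precision_score(cc2) * recall_score(cc2) /
                 (precision_score(cc2) + recall_score(cc2)))
  expect_equal(accuracy_score(cc2), 0.75)
})

test_that("zero denominators yield flagged zeros", {
  none_pred <- confusion_counts(c(0, 0), c(1, 0))
  p <- precision_score(none_pred)
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "undefined"))
  no_pos <- confusion_counts(c(0, 0), c(0, 0))
  expect_true(attr(recall_score(no_pos), "undefined"))
  expect_true(attr(f1_score(no_pos), "undefined"))
})

test_that("PR curves enumerate every decision threshold", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2)
  truth <- c(1, 1, 1, 0, 0)
  cv <- pr_curve(scores, truth)
  # perfect separation: precision 1 at every point up to full recall
  upto_full <- seq_len(min(which(cv$recall == 1)))
  expect_true(all(cv$precision[upto_full] == 1))
  expect_true(all(diff(cv$recall) >= 0))
  expect_equal(attr(cv, "baseline"), 3 / 5)
  expect_equal(attr(pr_curve(runif(20), c(rep(1, 5), rep(0, 15))),
                    "baseline"), 0.25)
  expect_error(pr_curve(runif(4), rep(0, 4)), "no positive")
})

test_that("PR curve matches the brute-force threshold sweep on n = 8", {
  set.seed(33)
  for (rep in 1:3) {
    scores <- round(runif(8), 2)
    truth <- rbinom(8, 1, 0.5)
    if (sum(truth) == 0) truth[1] <- 1
    cv <- pr_curve(scores, truth)
    ref <- oracle_pr(scores, truth)
    expect_equal(cv$threshold, ref$threshold)
    expect_equal(cv$precision, ref$precision)
    expect_equal(cv$recall, ref$recall)
    expect_equal(average_precision(cv),
                 oracle_ap(ref$precision, ref$recall))
  }
})

test_that("average precision has its closed-form extremes", {
  perfect <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(average_precision(perfect), 1)
  n <- 10
  worst <- pr_curve(seq(1, 0.1, length.out = n),
                    c(rep(0, n - 1), 1))
  expect_equal(average_precision(worst), 1 / n)
})

test_that("random scorers average to the class baseline", {
  set.seed(34)
  truth <- c(rep(1, 5), rep(0, 15))
  aps <- replicate(500, average_precision(pr_curve(runif(20), truth)))
  expect_lt(abs(mean(aps) - 0.25), 3 * stats::sd(aps))
})

test_that("PR curves are rank-invariant and constant scorers hit baseline", {
  set.seed(35)
  scores <- runif(30)
  truth <- rbinom(30, 1, 0.4)
  truth[1] <- 1
  a <- pr_curve(scores, truth)
  b <- pr_curve(exp(3 * scores), truth) # strictly monotone transform
  expect_equal(a$precision, b$precision)
  expect_equal(a$recall, b$recall)
  expect_equal(average_precision(a), average_precision(b))
  const <- pr_curve(rep(0.5, 30), truth)
  expect_equal(nrow(const), 1)
  expect_equal(const$precision, mean(truth))
})

test_that("reports aggregate per-class, macro, and across-fold metrics", {
  classes <- c("a", "b", "c")
  truth <- rep(classes, times = c(10, 6, 4))
  perfect <- matrix(0.05, 20, 3, dimnames = list(NULL, classes))
  for (i in seq_along(truth)) perfect[i, truth[i]] <- 0.9
  rep5 <- metrics_report(rep(list(perfect), 5), truth)
  expect_true(all(rep5$across_folds$sd == 0))
  expect_equal(glance(rep5)$f1, 1)
  expect_equal(glance(rep5)$accuracy, 1)
  expect_equal(tidy(rep5)$baseline, c(0.5, 0.3, 0.2))
  # macro F1 bounded by per-class extremes
  set.seed(36)
  noisy <- perfect + matrix(runif(60, 0, 0.6), 20, 3)
  noisy <- noisy / rowSums(noisy)
  colnames(noisy) <- classes
  repn <- metrics_report(noisy, truth)
  expect_lte(glance(repn)$f1, max(tidy(repn)$f1))
  expect_gte(glance(repn)$f1, min(tidy(repn)$f1))
  expect_error(metrics_report(list(perfect, perfect[1:5, ]), truth),
               "shape")
  expect_error(metrics_report(unname(perfect), truth), "named")
})

test_that("a learned classifier beats each class baseline on AP", {
  run <- gallery_run()
  pc <- tidy(run$report)
  expect_true(all(pc$average_precision >= pc$baseline))
})

test_that("plot methods return ggplot objects", {
  cv <- pr_curve(c(0.9, 0.4, 0.2), c(1, 0, 1), class = "demo")
  expect_s3_class(autoplot(cv), "ggplot")
  truth <- rep(c("a", "b"), each = 5)
  m <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  m <- m / rowSums(m)
  expect_s3_class(autoplot(metrics_report(m, truth)), "ggplot")
  pl <- dihm:::new_plane(1000, matrix(runif(16), 4, 4), 1)
  expect_s3_class(plot_plane(pl), "ggplot")
})
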