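#' One-vs-all binarization of multi-class labels
#'
#' Recasts a multi-class labeling as a binary task: 1 where the label
#' equals `positive_class`, 0 elsewhere. Binarizing against every class in
#' turn and summing gives the all-ones vector.
#'
#' @param labels Character or factor labels.
#' @param positive_class The class treated as positive; must belong to
#'   `levels`.
#' @param levels Known label set. Default: the distinct values of `labels`.
#' @return Integer 0/1 vector. Warns if the positive class is absent.
#' @export
binarize_labels <- function(labels, positive_class,
                            levels = unique(as.character(labels))) {
  labels <- as.character(labels)
  if (!positive_class %in% levels) {
    stop("unknown class: ", positive_class, call. = FALSE)
  }
  if (!positive_class %in% labels) {
    warning("positive class '", positive_class,
            "' absent from labels; all zeros")
  }
  as.integer(labels == positive_class)
}

#' 2x2 confusion counts
#'
#' @param predicted,truth Binary 0/1 vectors of equal length.
#' @return A `dihm_confusion` list with `tp`, `fp`, `fn`, `tn` (summing to
#'   the number of items).
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  structure(list(
    tp = sum(predicted == 1 & truth == 1),
    fp = sum(predicted == 1 & truth == 0),
    fn = sum(predicted == 0 & truth == 1),
    tn = sum(predicted == 0 & truth == 0)
  ), class = "dihm_confusion")
}

zero_flagged <- function() structure(0, undefined = TRUE)

#' Threshold metrics from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f1 = 2 * precision * recall / (precision + recall)`, and accuracy is
#' the total proportion of correct predictions. A zero denominator yields
#' 0 carrying an `undefined` attribute flag (documented convention, so
#' empty-prediction classes do not poison macro averages silently).
#'
#' @param counts A [confusion_counts()] object.
#' @return Scalar in `[0, 1]`.
#' @export
precision_score <- function(counts) {
  d <- counts$tp + counts$fp
  if (d == 0) return(zero_flagged())
  counts$tp / d
}

#' @rdname precision_score
#' @export
recall_score <- function(counts) {
  d <- counts$tp + counts$fn
  if (d == 0) return(zero_flagged())
  counts$tp / d
}

#' @rdname precision_score
#' @export
f1_score <- function(counts) {
  p <- precision_score(counts)
  r <- recall_score(counts)
  if (p + r == 0) return(zero_flagged())
  2 * (p * r) / (p + r)
}

#' @rdname precision_score
#' @export
accuracy_score <- function(counts) {
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  if (n == 0) return(zero_flagged())
  (counts$tp + counts$tn) / n
}

#' Precision-recall curve at every decision threshold
#'
#' One (precision, recall) point per unique score value, in descending
#' threshold order, predicting positive where `score >= threshold`; items
#' sharing a score enter the curve together. Recall is non-decreasing
#' along the sequence. The chance baseline for the class is the positive
#' prevalence `y = P / (P + N)`.
#'
#' @param scores Per-item real-valued scores (higher = more positive).
#' @param truth Binary 0/1 truth vector with at least one positive.
#' @param class Optional class label stored with the curve.
#' @return A `dihm_pr_curve` tibble (`threshold`, `precision`, `recall`)
#'   with attributes `baseline` and `class`.
#' @export
pr_curve <- function(scores, truth, class = NA_character_) {
  truth <- as.integer(truth)
  stopifnot(length(scores) == length(truth))
  p_total <- sum(truth == 1)
  if (p_total == 0) {
    stop("undefined curve: no positive items", call. = FALSE)
  }
  thresholds <- sort(unique(scores), decreasing = TRUE)
  o <- order(scores, decreasing = TRUE)
  s_sorted <- scores[o]
  cum_tp <- cumsum(truth[o] == 1)
  # index of the last item with score >= t, per unique threshold
  n_at <- findInterval(-thresholds, -s_sorted)
  tp <- cum_tp[n_at]
  curve <- tibble::tibble(
    threshold = thresholds,
    precision = tp / n_at,
    recall = tp / p_total
  )
  structure(curve, class = c("dihm_pr_curve", class(curve)),
            baseline = p_total / length(truth),
            positive_class = class)
}

#' Average precision (uninterpolated)
#'
#' The step-wise sum `AP = sum_n (R_n - R_{n-1}) * P_n` over the curve's
#' points with the convention `R_0 = 0`; no interpolation variant is
#' applied.
#'
#' @param curve A [pr_curve()].
#' @return Scalar in `(0, 1]`.
#' @export
average_precision <- function(curve) {
  sum(diff(c(0, curve$recall)) * curve$precision)
}

#' Evaluation report across classes and folds
#'
#' Computes, from per-fold score matrices and the shared truth labels:
#' per-class one-vs-all threshold metrics (labels assigned by row argmax
#' of the fold-ensemble mean scores), average precision and the class
#' baseline `P/(P+N)`; unweighted (macro) averages, which weight minority
#' classes equally; and across-fold mean and standard deviation of each
#' macro metric.
#'
#' @param score_matrices One score matrix (items x classes, columns named
#'   by class) or a list of them, one per fold, with identical shapes.
#' @param truth Character or factor truth labels, one per item.
#' @return A `dihm_report` with tibbles `per_class`, `macro`,
#'   `across_folds`.
#' @export
metrics_report <- function(score_matrices, truth) {
  if (is.matrix(score_matrices)) score_matrices <- list(score_matrices)
  truth <- as.character(truth)
  shapes <- vapply(score_matrices, function(m) paste(dim(m), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1) {
    stop("fold score matrices must share one shape", call. = FALSE)
  }
  if (nrow(score_matrices[[1]]) != length(truth)) {
    stop("score rows must match truth length", call. = FALSE)
  }
  classes <- colnames(score_matrices[[1]])
  if (is.null(classes)) {
    stop("score matrix columns must be named by class", call. = FALSE)
  }
  ens <- Reduce(`+`, score_matrices) / length(score_matrices)
  per_class <- dplyr::bind_rows(lapply(classes, function(cls) {
    truth_bin <- as.integer(truth == cls)
    pred_bin <- as.integer(classes[max.col(ens, ties.method = "first")] == cls)
    cc <- confusion_counts(pred_bin, truth_bin)
    ap <- if (sum(truth_bin) > 0) {
      average_precision(pr_curve(ens[, cls], truth_bin, class = cls))
    } else {
      NA_real_
    }
    tibble::tibble(
      class = cls,
      n = sum(truth_bin),
      precision = as.numeric(precision_score(cc)),
      recall = as.numeric(recall_score(cc)),
      f1 = as.numeric(f1_score(cc)),
      average_precision = ap,
      baseline = mean(truth_bin)
    )
  }))
  fold_macro <- dplyr::bind_rows(lapply(seq_along(score_matrices),
                                        function(i) {
    m <- macro_metrics(score_matrices[[i]], truth, classes)
    m$fold <- i - 1L
    m
  }))
  across_folds <- fold_macro |>
    tidyr::pivot_longer(c("accuracy", "precision", "recall", "f1"),
                        names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
                     .groups = "drop")
  structure(list(per_class = per_class,
                 macro = macro_metrics(ens, truth, classes),
                 across_folds = across_folds,
                 n = length(truth)),
            class = "dihm_report")
}

macro_metrics <- function(scores, truth, classes) {
  pred <- classes[max.col(scores, ties.method = "first")]
  per <- vapply(classes, function(cls) {
    cc <- confusion_counts(as.integer(pred == cls),
                           as.integer(truth == cls))
    c(precision = as.numeric(precision_score(cc)),
      recall = as.numeric(recall_score(cc)),
      f1 = as.numeric(f1_score(cc)))
  }, numeric(3))
  tibble::tibble(
    accuracy = mean(pred == truth),
    precision = mean(per["precision", ]),
    recall = mean(per["recall", ]),
    f1 = mean(per["f1", ])
  )
}

#' @export
print.dihm_report <- function(x, ...) {
  cat(sprintf("<dihm_report> %d items, %d classes\n",
              x$n, nrow(x$per_class)))
  cat(sprintf("  macro: acc %.3f  prec %.3f  rec %.3f  f1 %.3f\n",
              x$macro$accuracy, x$macro$precision, x$macro$recall,
              x$macro$f1))
  invisible(x)
}

#' Tidy per-class metrics of a report
#'
#' @param x A `dihm_report`.
#' @param ... Unused.
#' @return The `per_class` tibble.
#' @method tidy dihm_report
#' @export
tidy.dihm_report <- function(x, ...) x$per_class

#' One-row macro summary of a report
#'
#' @param x A `dihm_report`.
#' @param ... Unused.
#' @return Tibble with macro accuracy/precision/recall/f1 and `n`.
#' @method glance dihm_report
#' @export
glance.dihm_report <- function(x, ...) {
  dplyr::mutate(x$macro, n = x$n)
}
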