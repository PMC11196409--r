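#' Confusion matrix from label vectors
#'
#' @param truth true class labels, 0-based integers below `n_classes`.
#' @param predicted predicted class labels, same length and range.
#' @param n_classes number of classes (defaults to the largest label + 1).
#' @return A `confusion_matrix`: an `n_classes` x `n_classes` integer matrix,
#'   rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, n_classes = NULL) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.",
          class = "braincdnet_input_error")
  }
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (is.null(n_classes)) n_classes <- max(truth, predicted) + 1L
  n_classes <- as.integer(n_classes)
  if (any(truth < 0 | truth >= n_classes | predicted < 0 | predicted >= n_classes)) {
    abort("labels must lie in [0, n_classes).", class = "braincdnet_input_error")
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, predicted[i] + 1L] <- cm[truth[i] + 1L, predicted[i] + 1L] + 1L
  }
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

# percentage helper: undefined ratios (0/0) become NA, never 0
pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Binary classification metrics from a 2x2 confusion matrix
#'
#' Computes, as percentages: sensitivity `TPR = TP/(TP+FN)`, specificity
#' `TNR = TN/(TN+FP)`, precision `PPV = TP/(TP+FP)`, the F-score (harmonic
#' mean of PPV and TPR) and accuracy `(TP+TN)/total`. A metric whose
#' denominator is empty is reported as `NA` (undefined), not as 0.
#'
#' @param cm a 2x2 `confusion_matrix` (or plain matrix); by convention the
#'   second row/column is the positive class.
#' @param positive 0-based index of the positive class (default 1).
#' @return A one-row tibble with columns `tpr`, `tnr`, `ppv`, `f_score`,
#'   `accuracy` (percent).
#' @export
binary_metrics <- function(cm, positive = 1L) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || !all(dim(cm) == 2)) {
    abort("`cm` must be a 2x2 matrix.", class = "braincdnet_input_error")
  }
  p <- positive + 1L
  n <- 3L - p
  tp <- cm[p, p]; fn <- cm[p, n]; fp <- cm[n, p]; tn <- cm[n, n]
  tpr <- pct(tp, tp + fn)
  tnr <- pct(tn, tn + fp)
  ppv <- pct(tp, tp + fp)
  f <- if (is.na(tpr) || is.na(ppv) || (tpr + ppv) == 0) NA_real_ else
    2 * ppv * tpr / (ppv + tpr)
  tibble(tpr = tpr, tnr = tnr, ppv = ppv, f_score = f,
         accuracy = pct(tp + tn, sum(cm)))
}

#' One-vs-rest per-class metrics with macro averages
#'
#' Reduces a C-class confusion matrix to C binary problems (class c vs the
#' rest), computes [binary_metrics()] for each, and appends a `"macro"` row
#' holding the unweighted arithmetic mean of the per-class values — the
#' averaging rule behind the published per-scheme "Average" rows. The
#' overall multiclass accuracy, `trace(cm)/total`, is attached as the
#' `overall_accuracy` attribute.
#'
#' @param cm a C x C `confusion_matrix` (C >= 2).
#' @param class_names optional class names for the `class` column.
#' @return A `metrics_report` tibble with columns `class`, `tpr`, `tnr`,
#'   `ppv`, `f_score`, `accuracy`.
#' @export
per_class_metrics_ovr <- function(cm, class_names = NULL) {
  cm <- unclass(cm)
  C <- nrow(cm)
  stopifnot(is.matrix(cm), C == ncol(cm), C >= 2)
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(C) - 1L)
  per <- purrr::map_dfr(seq_len(C), function(c) {
    tp <- cm[c, c]
    fn <- sum(cm[c, ]) - tp
    fp <- sum(cm[, c]) - tp
    tn <- sum(cm) - tp - fn - fp
    binary_metrics(matrix(c(tn, fn, fp, tp), 2, 2), positive = 1L)
  })
  per <- dplyr::bind_cols(tibble(class = class_names), per)
  macro <- dplyr::summarise(per, dplyr::across(dplyr::where(is.numeric), mean))
  out <- dplyr::bind_rows(per, dplyr::bind_cols(tibble(class = "macro"), macro))
  attr(out, "overall_accuracy") <- 100 * sum(diag(cm)) / sum(cm)
  class(out) <- c("metrics_report", class(out))
  out
}

positive_scores <- function(scores, positive_class) {
  if (is.matrix(scores)) scores[, positive_class + 1L] else as.numeric(scores)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg`: the probability that a random positive sample scores
#' above a random negative one, with ties credited 0.5.
#'
#' @param truth per-sample true class labels (0-based integers).
#' @param scores either a numeric vector of scores for the positive class,
#'   or an n x C matrix of class scores (rows summing to 1) from which the
#'   positive class's column is taken.
#' @param positive_class 0-based index of the positive class (default 1);
#'   all other classes count as negative (one-vs-rest).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(truth, scores, positive_class = 1L) {
  s <- positive_scores(scores, positive_class)
  pos <- as.integer(truth) == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC is undefined without both positive and negative samples.",
          class = "braincdnet_input_error")
  }
  r <- rank(s)  # average ranks give ties 0.5 credit
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the observed scores (descending) and
#' records one `(fpr, tpr)` point per distinct score, starting at `(0, 0)`
#' and ending at `(1, 1)`. The trapezoidal area under these points equals
#' [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return A `roc_curve` tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(truth, scores, positive_class = 1L) {
  s <- positive_scores(scores, positive_class)
  pos <- as.integer(truth) == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC is undefined without both positive and negative samples.",
          class = "braincdnet_input_error")
  }
  ord <- order(s, decreasing = TRUE)
  s_ord <- s[ord]; pos_ord <- pos[ord]
  keep <- c(s_ord[-length(s_ord)] != s_ord[-1], TRUE)  # last index of each distinct score
  tp <- cumsum(pos_ord)[keep]
  fpn <- cumsum(!pos_ord)[keep]
  out <- tibble(threshold = c(Inf, s_ord[keep]),
                fpr = c(0, fpn / n_neg),
                tpr = c(0, tp / n_pos))
  class(out) <- c("roc_curve", class(out))
  out
}

#' Trapezoidal area under a ROC curve
#'
#' @param curve a `roc_curve` tibble.
#' @return area in `[0, 1]`.
#' @export
auc_trapezoid <- function(curve) {
  x <- curve$fpr; y <- curve$tpr
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' One-vs-rest AUC for every class
#'
#' @param truth 0-based true labels.
#' @param scores n x C score matrix.
#' @return tibble with columns `class_index` (0-based) and `auc`.
#' @export
multiclass_auc <- function(truth, scores) {
  stopifnot(is.matrix(scores))
  purrr::map_dfr(seq_len(ncol(scores)) - 1L, function(c) {
    tibble(class_index = c, auc = roc_auc(truth, scores, positive_class = c))
  })
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", auc_trapezoid(object)))
}

#' @export
autoplot.metrics_report <- function(object, ...) {
  long <- tidyr_pivot(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::coord_cartesian(ylim = c(0, 100))
}

# minimal wide-to-long reshape (avoids importing tidyr for one call)
tidyr_pivot <- function(report) {
  metrics <- names(report)[vapply(report, is.numeric, logical(1))]
  purrr::map_dfr(metrics, function(m) {
    tibble(class = report$class, metric = m, value = report[[m]])
  })
}
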