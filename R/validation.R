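#' Stratified k-fold split plan
#'
#' Assigns every sample to one of `k` folds such that within each class the
#' fold sizes differ by at most one, and the total fold sizes stay balanced
#' (each class's remainder samples go to the currently smallest folds).
#' The assignment is deterministic given `seed`.
#'
#' @param labels per-sample class labels (factor, character or integer).
#' @param k number of folds (>= 2); the headline scheme uses `k = 5`.
#' @param seed integer RNG seed; recorded in the plan. The caller's RNG
#'   state is left untouched.
#' @return A `split_plan` tibble with columns `index`, `class`, `fold` and
#'   attributes `scheme = "kfold"`, `k`, `seed`.
#' @export
kfold_split <- function(labels, k = 5L, seed = 1L) {
  if (!is.numeric(k) || length(k) != 1 || k < 2) {
    abort("`k` must be an integer >= 2.", class = "braincdnet_parameter_error")
  }
  k <- as.integer(k)
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    abort(sprintf("every class needs at least k = %d samples for stratified %d-fold splitting.",
                  k, k),
          class = "braincdnet_stratification_error")
  }
  fold <- integer(length(labels))
  fold_totals <- integer(k)
  withr::with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      n_c <- length(idx)
      base <- n_c %/% k
      rem <- n_c %% k
      counts <- rep(base, k)
      if (rem > 0) {
        # remainder goes to the folds that are currently smallest
        target <- order(fold_totals, seq_len(k))[seq_len(rem)]
        counts[target] <- counts[target] + 1L
      }
      fold[idx] <- rep(seq_len(k), times = counts)
      fold_totals <- fold_totals + counts
    }
  })
  structure(
    tibble(index = seq_along(labels), class = labels, fold = fold),
    scheme = "kfold", k = k, seed = as.integer(seed),
    class = c("split_plan", class(tibble())))
}

#' Stratified holdout split plan
#'
#' Randomly partitions the samples into a training and a test set, keeping
#' every class present on both sides. Per class, the training count is
#' `round-half-up(class size * train_fraction)`; the remainder goes to the
#' test set. Deterministic given `seed`.
#'
#' @inheritParams kfold_split
#' @param train_fraction fraction of each class assigned to training,
#'   strictly between 0 and 1. The published holdout cases use 0.75 and 0.85.
#' @return A `split_plan` tibble with columns `index`, `class`, `partition`
#'   (`"train"`/`"test"`) and attributes `scheme = "holdout"`,
#'   `train_fraction`, `seed`.
#' @export
holdout_split <- function(labels, train_fraction = 0.85, seed = 1L) {
  if (!is.numeric(train_fraction) || length(train_fraction) != 1 ||
      train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.",
          class = "braincdnet_parameter_error")
  }
  labels <- as.character(labels)
  tab <- table(labels)
  part <- character(length(labels))
  withr::with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      n_c <- length(idx)
      n_train <- floor(n_c * train_fraction + 0.5)  # round half up
      if (n_train < 1 || n_train >= n_c) {
        abort(sprintf("train_fraction = %g leaves class '%s' empty on one side.",
                      train_fraction, cl),
              class = "braincdnet_stratification_error")
      }
      part[idx[seq_len(n_train)]] <- "train"
      part[idx[-seq_len(n_train)]] <- "test"
    }
  })
  structure(
    tibble(index = seq_along(labels), class = labels, partition = part),
    scheme = "holdout", train_fraction = train_fraction, seed = as.integer(seed),
    class = c("split_plan", class(tibble())))
}

#' Average metric reports across cross-validation folds
#'
#' Element-wise arithmetic mean of per-fold metric reports (the k-fold
#' aggregation rule: the average over the k runs). All reports must share
#' the same rows and metric columns; `NA` metrics (undefined in some fold)
#' propagate to `NA`.
#'
#' @param reports list of metric tibbles as produced by [binary_metrics()]
#'   or [per_class_metrics_ovr()].
#' @return A single report of the same shape, averaged; if the inputs carry
#'   an `overall_accuracy` attribute it is averaged as well.
#' @export
aggregate_cv_metrics <- function(reports) {
  if (!is.list(reports) || length(reports) < 1) {
    abort("`reports` must be a non-empty list of metric reports.",
          class = "braincdnet_aggregation_error")
  }
  ref <- reports[[1]]
  num_cols <- names(ref)[vapply(ref, is.numeric, logical(1))]
  key_cols <- setdiff(names(ref), num_cols)
  for (r in reports[-1]) {
    same_keys <- all(vapply(key_cols, function(k) {
      identical(unname(r[[k]]), unname(ref[[k]]))
    }, logical(1)))
    if (!identical(names(r), names(ref)) || !same_keys ||
        nrow(r) != nrow(ref)) {
      abort("all reports must share the same rows and metric keys.",
            class = "braincdnet_aggregation_error")
    }
  }
  out <- ref
  for (col in num_cols) {
    out[[col]] <- rowMeans(do.call(cbind, lapply(reports, `[[`, col)))
  }
  oa <- lapply(reports, attr, "overall_accuracy")
  if (!any(vapply(oa, is.null, logical(1)))) {
    attr(out, "overall_accuracy") <- mean(unlist(oa))
  }
  out
}

#' Export a split plan as CSV
#'
#' @param plan a `split_plan`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  utils::write.csv(as.data.frame(plan), path, row.names = FALSE)
  invisible(path)
}
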