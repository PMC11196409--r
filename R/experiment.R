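#' Run a full classification experiment
#'
#' End-to-end orchestration: preprocess the dataset (with or without the
#' Nimble filter, per the config's ablation switch), partition it with the
#' requested validation scheme, train a freshly initialized model per
#' fold/holdout, evaluate on the held-out samples, and aggregate. All seeds,
#' the resolved configuration and the split plan are kept in the result.
#'
#' @param data either a `labeled_dataset` (from [generate_dataset()] or
#'   [load_image_dataset()]) or a [phantom_spec()] (generated on the fly).
#' @param scheme `"holdout"` (default) or `"kfold"`.
#' @param k folds for the k-fold scheme; default 5.
#' @param train_fraction training fraction for the holdout scheme; the
#'   published cases are 0.75 and 0.85 (default).
#' @param config a [training_config()]; its `seed` drives the split and
#'   per-fold initialization, `sharpen`/`alpha` drive preprocessing.
#' @param arch optional `cdnet_architecture`; defaults to the BrainCDNet
#'   build matching the data's class count and image side.
#' @param verbose print progress?
#' @return A `cdnet_run`: list with `scheme`, `split` (the `split_plan`),
#'   `fold_results` (list of [evaluate_model()] outputs), `metrics`
#'   (aggregated report), `overall_accuracy`, `histories`, `config`.
#' @export
run_experiment <- function(data, scheme = c("holdout", "kfold"), k = 5L,
                           train_fraction = 0.85,
                           config = training_config(), arch = NULL,
                           verbose = FALSE) {
  scheme <- match.arg(scheme)
  if (inherits(data, "phantom_spec")) data <- generate_dataset(data)
  stopifnot(inherits(data, "labeled_dataset"))
  n_classes <- length(data$class_names)
  side <- nrow(data$images[[1]])
  if (is.null(arch)) arch <- build_brain_cdnet(n_classes, input_side = side)

  prep <- prepare_dataset(data, alpha = config$alpha, sharpen = config$sharpen,
                          boundary = config$boundary, side = arch$input_shape[1])
  labels <- data$class_names[prep$y + 1L]

  split <- if (scheme == "kfold") {
    kfold_split(labels, k = k, seed = config$seed)
  } else {
    holdout_split(labels, train_fraction = train_fraction, seed = config$seed)
  }
  folds <- if (scheme == "kfold") seq_len(k) else 1L

  fold_results <- list()
  histories <- list()
  for (f in folds) {
    test_idx <- if (scheme == "kfold") split$index[split$fold == f] else
      split$index[split$partition == "test"]
    train_idx <- setdiff(split$index, test_idx)
    if (verbose) {
      message(sprintf("[%s] fold %d: %d train / %d test",
                      scheme, f, length(train_idx), length(test_idx)))
    }
    fold_config <- config
    fold_config$seed <- config$seed + f - 1L  # fresh init per fold
    model <- train_model(arch,
                         prep$x[, , , train_idx, drop = FALSE],
                         prep$y[train_idx],
                         config = fold_config,
                         class_names = data$class_names,
                         verbose = verbose)
    fold_results[[f]] <- evaluate_model(model,
                                        prep$x[, , , test_idx, drop = FALSE],
                                        prep$y[test_idx])
    histories[[f]] <- model$history
  }

  metrics <- aggregate_cv_metrics(purrr::map(fold_results, "metrics"))
  structure(
    list(scheme = scheme, k = if (scheme == "kfold") as.integer(k) else NULL,
         train_fraction = if (scheme == "holdout") train_fraction else NULL,
         split = split, fold_results = fold_results, metrics = metrics,
         overall_accuracy = mean(purrr::map_dbl(fold_results, "overall_accuracy")),
         histories = histories, config = config,
         class_names = data$class_names),
    class = "cdnet_run")
}

#' @export
print.cdnet_run <- function(x, ...) {
  lab <- if (x$scheme == "kfold") sprintf("%d-fold CV", x$k) else
    sprintf("holdout %.0f/%.0f", 100 * x$train_fraction,
            100 * (1 - x$train_fraction))
  cat(sprintf("<cdnet_run> %s, %s Nimble filter\n", lab,
              if (x$config$sharpen) "with" else "without"))
  cat(sprintf("  overall accuracy: %.2f%%\n", x$overall_accuracy))
  print(x$metrics)
  invisible(x)
}

#' @rdname run_experiment
#' @param x a `cdnet_run` (for the `tidy`/`glance` methods).
#' @param ... unused.
#' @export
tidy.cdnet_run <- function(x, ...) {
  purrr::imap_dfr(x$fold_results, function(res, f) {
    dplyr::bind_cols(tibble(fold = f), res$metrics)
  })
}

#' @rdname run_experiment
#' @export
glance.cdnet_run <- function(x, ...) {
  tibble(scheme = x$scheme,
         folds = length(x$fold_results),
         sharpen = x$config$sharpen,
         overall_accuracy = x$overall_accuracy)
}

#' Training-history plot for an experiment run
#' @param object a `cdnet_run`.
#' @param ... unused.
#' @export
autoplot.cdnet_run <- function(object, ...) {
  hist <- purrr::imap_dfr(object$histories, function(h, f) {
    dplyr::bind_cols(tibble(fold = factor(f)), h)
  })
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$fold)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss")
}
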