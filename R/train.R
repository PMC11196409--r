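#' Training configuration
#'
#' The published training protocol: Adam with learning rate 0.001, batch
#' size 64, 50 epochs, categorical cross-entropy, He-Normal weight
#' initialization. `epochs` is routinely reduced for desk-scale runs.
#'
#' @param learning_rate Adam step size (> 0); default 0.001.
#' @param batch_size mini-batch size (>= 1); default 64.
#' @param epochs training epochs (>= 1); default 50.
#' @param seed integer seed controlling weight initialization and batch
#'   shuffling.
#' @param sharpen apply the Nimble filter during preprocessing? `FALSE`
#'   selects the ablation arm.
#' @param alpha Nimble sharpening strength; default 2.
#' @param boundary Nimble boundary policy.
#' @param double_precision run the engine in double instead of single
#'   precision (slower; used for numerical checks).
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.001, batch_size = 64L,
                            epochs = 50L, seed = 1L, sharpen = TRUE,
                            alpha = 2, boundary = "replicate",
                            double_precision = FALSE) {
  if (learning_rate < 0) {
    abort("`learning_rate` must be >= 0.", class = "braincdnet_parameter_error")
  }
  if (batch_size < 1 || epochs < 1) {
    abort("`batch_size` and `epochs` must be >= 1.",
          class = "braincdnet_parameter_error")
  }
  structure(
    list(optimizer = "adam", learning_rate = learning_rate,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         loss = "categorical_crossentropy", init = "he_normal",
         seed = as.integer(seed), sharpen = isTRUE(sharpen), alpha = alpha,
         boundary = boundary, double_precision = isTRUE(double_precision)),
    class = "training_config")
}

# He-Normal initial weights for every trainable tensor of the architecture
# (sd = sqrt(2 / fan_in) on conv and dense kernels; batch-norm scale 1,
# shift 0; biases 0; running stats at their neutral values).
he_normal_weights <- function(num_classes) {
  w <- list()
  conv <- function(name, kh, kw, cin, cout) {
    sd <- sqrt(2 / (kh * kw * cin))
    w[[paste0(name, ".W")]] <<- array(rnorm(kh * kw * cin * cout, 0, sd),
                                      dim = c(kh, kw, cin, cout))
    w[[paste0(name, ".b")]] <<- numeric(cout)
  }
  bn <- function(name, C) {
    w[[paste0(name, ".gamma")]] <<- rep(1, C)
    w[[paste0(name, ".beta")]] <<- numeric(C)
    w[[paste0(name, ".running_mean")]] <<- numeric(C)
    w[[paste0(name, ".running_var")]] <<- rep(1, C)
  }
  for (i in 1:4) {
    conv(paste0("a", i, "_conv"), 3, 3, 3, 64)
    bn(paste0("a", i, "_bn"), 64)
  }
  for (j in 1:2) {
    conv(paste0("b", j, "_conv3"), 3, 3, 128, 128)
    bn(paste0("b", j, "_bn1"), 128)
    conv(paste0("b", j, "_conv1"), 1, 1, 128, 128)
    bn(paste0("b", j, "_bn2"), 128)
  }
  conv("c_conv3", 3, 3, 256, 256)
  bn("c_bn1", 256)
  conv("c_conv1", 1, 1, 256, 256)
  bn("c_bn2", 256)
  w[["head.W"]] <- matrix(rnorm(256 * num_classes, 0, sqrt(2 / 256)),
                          256, num_classes)
  w[["head.b"]] <- numeric(num_classes)
  w
}

#' Train a BrainCDNet model
#'
#' Materializes the architecture in the training engine, initializes
#' weights with He-Normal draws, and runs mini-batch Adam on the softmax
#' cross-entropy loss. Weights are freshly initialized on every call
#' (as required for valid cross-validation).
#'
#' @param arch a `cdnet_architecture` from [build_brain_cdnet()]; its
#'   `num_classes` and input side define the materialized network.
#' @param x prepared inputs: `side` x `side` x 3 x n array in `[0, 1]`
#'   (see [prepare_dataset()]).
#' @param y 0-based integer labels, length n.
#' @param config a [training_config()].
#' @param class_names optional class names carried into reports.
#' @param verbose print per-epoch loss/accuracy?
#' @return A `cdnet_model`: list with the engine handle, `history`
#'   (tibble of `epoch`, `loss`, `accuracy`), `arch`, `config`,
#'   `class_names`.
#' @export
train_model <- function(arch, x, y, config = training_config(),
                        class_names = NULL, verbose = FALSE) {
  stopifnot(inherits(arch, "cdnet_architecture"),
            inherits(config, "training_config"))
  d <- dim(x)
  if (length(d) != 4 || d[1] != d[2] || d[3] != 3) {
    abort("`x` must be a side x side x 3 x n array.",
          class = "braincdnet_configuration_error")
  }
  if (d[1] != arch$input_shape[1]) {
    abort(sprintf("input side %d does not match the architecture input %d.",
                  d[1], arch$input_shape[1]),
          class = "braincdnet_configuration_error")
  }
  y <- as.integer(y)
  n <- d[4]
  if (length(y) != n || any(y < 0 | y >= arch$num_classes)) {
    abort("`y` must hold 0-based labels below num_classes, one per image.",
          class = "braincdnet_configuration_error")
  }
  ptr <- cdnet_create(arch$num_classes, d[1], config$double_precision)
  history <- NULL
  withr::with_seed(config$seed, {
    cdnet_set_weights(ptr, he_normal_weights(arch$num_classes))
    history <- purrr::map_dfr(seq_len(config$epochs), function(ep) {
      ord <- sample(n)
      starts <- seq(1, n, by = config$batch_size)
      stats <- purrr::map_dfr(starts, function(s) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        res <- cdnet_train_batch(ptr, x[, , , idx, drop = FALSE], y[idx],
                                 lr = config$learning_rate)
        tibble(n = length(idx), loss = res$loss, accuracy = res$accuracy)
      })
      ep_loss <- sum(stats$loss * stats$n) / sum(stats$n)
      ep_acc <- sum(stats$accuracy * stats$n) / sum(stats$n)
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f  accuracy %.3f",
                        ep, config$epochs, ep_loss, ep_acc))
      }
      tibble(epoch = ep, loss = ep_loss, accuracy = ep_acc)
    })
    # re-estimate batch-norm running statistics under the final weights so
    # inference-mode normalization matches what training converged to
    cdnet_refresh_stats(ptr, x, chunk = config$batch_size)
  })
  structure(
    list(ptr = ptr, history = history, arch = arch, config = config,
         class_names = class_names %||%
           paste0("class_", seq_len(arch$num_classes) - 1L)),
    class = "cdnet_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cdnet_model <- function(x, ...) {
  cat(sprintf("<cdnet_model> %d classes, input side %d, %d epochs trained\n",
              x$arch$num_classes, x$arch$input_shape[1], nrow(x$history)))
  cat(sprintf("  final training loss %.4f, accuracy %.3f\n",
              dplyr::last(x$history$loss), dplyr::last(x$history$accuracy)))
  invisible(x)
}

#' @export
predict.cdnet_model <- function(object, x, ...) {
  probs <- cdnet_predict(object$ptr, x)
  colnames(probs) <- object$class_names
  probs
}

#' @rdname train_model
#' @param x a `cdnet_model` (for the `tidy`/`glance` methods).
#' @param ... unused.
#' @export
tidy.cdnet_model <- function(x, ...) x$history

#' @rdname train_model
#' @export
glance.cdnet_model <- function(x, ...) {
  tibble(epochs = nrow(x$history),
         final_loss = dplyr::last(x$history$loss),
         final_accuracy = dplyr::last(x$history$accuracy),
         num_classes = x$arch$num_classes)
}

#' Evaluate a trained model on a test set
#'
#' Runs the network in inference mode, takes the arg-max class (ties broken
#' toward the lowest class index), and assembles the full metric battery:
#' the confusion matrix, per-class one-vs-rest metrics with macro averages
#' (or plain binary metrics for two classes), and one-vs-rest AUCs from the
#' softmax scores.
#'
#' @param model a `cdnet_model`.
#' @param x prepared test inputs (same layout as training).
#' @param y 0-based true labels.
#' @return list with `metrics` (report tibble incl. `auc` column),
#'   `overall_accuracy` (percent), `confusion` and `scores` (tibble of
#'   truth, prediction and per-class softmax scores).
#' @export
evaluate_model <- function(model, x, y) {
  stopifnot(inherits(model, "cdnet_model"))
  if (length(dim(x)) != 4 || dim(x)[4] < 1) {
    abort("test set must be a non-empty side x side x 3 x n array.",
          class = "braincdnet_input_error")
  }
  y <- as.integer(y)
  probs <- predict(model, x)
  pred <- max.col(probs, ties.method = "first") - 1L
  C <- model$arch$num_classes
  cm <- confusion_matrix(y, pred, n_classes = C)
  aucs <- vapply(seq_len(C) - 1L, function(c) {
    if (all(y == c) || !any(y == c)) NA_real_ else 100 * roc_auc(y, probs, c)
  }, numeric(1))
  if (C == 2L) {
    metrics <- binary_metrics(cm, positive = 1L)
    metrics <- dplyr::bind_cols(tibble(class = model$class_names[2]), metrics)
    metrics$auc <- aucs[2]
    attr(metrics, "overall_accuracy") <- 100 * sum(diag(cm)) / sum(cm)
    class(metrics) <- c("metrics_report", class(metrics))
  } else {
    metrics <- per_class_metrics_ovr(cm, class_names = model$class_names)
    metrics$auc <- c(aucs, mean(aucs))
  }
  scores <- as_tibble(probs, .name_repair = "minimal")
  names(scores) <- paste0("score_", model$class_names)
  scores <- dplyr::bind_cols(
    tibble(truth = y, predicted = pred), scores)
  list(metrics = metrics,
       overall_accuracy = 100 * sum(diag(cm)) / sum(cm),
       confusion = cm, scores = scores)
}
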