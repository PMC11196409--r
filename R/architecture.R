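#' Build the BrainCDNet layer graph
#'
#' Constructs the concatenated three-block architecture as a declarative
#' directed acyclic graph of layers, without materializing any weights.
#'
#' Block 1 applies four parallel ConvNetA units to the shared input (3x3
#' convolution, 64 filters, stride 2, bias; SELU; batch norm; 2x2 max-pool
#' stride 2); the top pair and the bottom pair of outputs are concatenated
#' channel-wise. Block 2 applies one ConvNetB unit per pair (3x3 convolution,
#' 128 filters + SELU + batch norm, then 1x1 convolution, 128 filters + SELU
#' + batch norm + 2x2 max-pool) and concatenates the two results. Block 3 is
#' a single ConvNetC (3x3 then 1x1 convolution, 256 filters each, GELU +
#' batch norm after each). Global average pooling reduces the final feature
#' map to a 256-vector feeding a softmax head.
#'
#' @param num_classes number of output classes (>= 2). The published
#'   parameter totals correspond to `num_classes = 3`.
#' @param input_side spatial edge length of the (square, 3-channel) input;
#'   default 224.
#' @return An object of class `cdnet_architecture`: a list with `layers`
#'   (a tibble, one row per layer), `num_classes` and `input_shape`.
#' @examples
#' arch <- build_brain_cdnet(3)
#' count_parameters(arch)
#' @export
build_brain_cdnet <- function(num_classes, input_side = 224L) {
  if (!is.numeric(num_classes) || length(num_classes) != 1 || num_classes < 2) {
    abort("`num_classes` must be an integer >= 2.",
          class = "braincdnet_parameter_error")
  }
  num_classes <- as.integer(num_classes)

  rows <- list()
  add <- function(id, kind, inputs, kernel = c(NA, NA), stride = NA_integer_,
                  filters = NA_integer_, activation = NA_character_,
                  use_bias = NA) {
    rows[[length(rows) + 1L]] <<- tibble(
      id = id, kind = kind,
      kernel_h = as.integer(kernel[1]), kernel_w = as.integer(kernel[2]),
      stride = as.integer(stride), filters = as.integer(filters),
      activation = activation, use_bias = use_bias,
      inputs = list(inputs))
  }

  add("input", "input", character(0))
  # Block 1: four parallel ConvNetA units on the shared input
  for (i in 1:4) {
    a <- paste0("a", i)
    add(paste0(a, "_conv"), "conv", "input", c(3, 3), 2L, 64L, use_bias = TRUE)
    add(paste0(a, "_selu"), "activation", paste0(a, "_conv"), activation = "selu")
    add(paste0(a, "_bn"), "batch_norm", paste0(a, "_selu"))
    add(paste0(a, "_pool"), "max_pool", paste0(a, "_bn"), c(2, 2), 2L)
  }
  # Top pair and bottom pair, by declaration order
  add("concat_top", "concat", c("a1_pool", "a2_pool"))
  add("concat_bottom", "concat", c("a3_pool", "a4_pool"))
  # Block 2: one ConvNetB per pair
  pair_in <- c("concat_top", "concat_bottom")
  for (j in 1:2) {
    b <- paste0("b", j)
    add(paste0(b, "_conv3"), "conv", pair_in[j], c(3, 3), 1L, 128L, use_bias = TRUE)
    add(paste0(b, "_selu1"), "activation", paste0(b, "_conv3"), activation = "selu")
    add(paste0(b, "_bn1"), "batch_norm", paste0(b, "_selu1"))
    add(paste0(b, "_conv1"), "conv", paste0(b, "_bn1"), c(1, 1), 1L, 128L, use_bias = TRUE)
    add(paste0(b, "_selu2"), "activation", paste0(b, "_conv1"), activation = "selu")
    add(paste0(b, "_bn2"), "batch_norm", paste0(b, "_selu2"))
    add(paste0(b, "_pool"), "max_pool", paste0(b, "_bn2"), c(2, 2), 2L)
  }
  add("concat_b", "concat", c("b1_pool", "b2_pool"))
  # Block 3: ConvNetC
  add("c_conv3", "conv", "concat_b", c(3, 3), 1L, 256L, use_bias = TRUE)
  add("c_gelu1", "activation", "c_conv3", activation = "gelu")
  add("c_bn1", "batch_norm", "c_gelu1")
  add("c_conv1", "conv", "c_bn1", c(1, 1), 1L, 256L, use_bias = TRUE)
  add("c_gelu2", "activation", "c_conv1", activation = "gelu")
  add("c_bn2", "batch_norm", "c_gelu2")
  add("gap", "global_avg_pool", "c_bn2")
  add("head", "dense_softmax", "gap", filters = num_classes,
      activation = "softmax", use_bias = TRUE)

  structure(
    list(layers = dplyr::bind_rows(rows),
         num_classes = num_classes,
         input_shape = c(as.integer(input_side), as.integer(input_side), 3L)),
    class = "cdnet_architecture"
  )
}

#' @export
print.cdnet_architecture <- function(x, ...) {
  cat(sprintf("<cdnet_architecture> %d layers, %d classes, input %s\n",
              nrow(x$layers), x$num_classes,
              paste(x$input_shape, collapse = "x")))
  audit <- count_parameters(x)
  cat(sprintf("  parameters: %s trainable + %s non-trainable = %s\n",
              format(audit$trainable_total, big.mark = ","),
              format(audit$non_trainable_total, big.mark = ","),
              format(audit$grand_total, big.mark = ",")))
  invisible(x)
}

# Resolve the number of channels flowing out of every layer by walking the
# DAG in declaration order (which is topological by construction).
layer_channels <- function(arch) {
  layers <- arch$layers
  ch <- setNames(rep(NA_integer_, nrow(layers)), layers$id)
  for (i in seq_len(nrow(layers))) {
    l <- layers[i, ]
    ins <- l$inputs[[1]]
    if (any(!ins %in% names(ch)) || anyNA(ch[ins])) {
      if (l$kind != "input") {
        abort(sprintf("layer '%s' has unresolved inputs.", l$id),
              class = "braincdnet_graph_error")
      }
    }
    ch[l$id] <- switch(l$kind,
      input = arch$input_shape[3],
      conv = l$filters,
      dense_softmax = l$filters,
      concat = sum(ch[ins]),
      ch[ins[1]]  # pass-through kinds
    )
  }
  ch
}

#' Count trainable and non-trainable parameters of an architecture
#'
#' Walks the layer graph and applies the standard counting conventions:
#' a convolution contributes `kh*kw*c_in*c_out` weights plus `c_out` biases
#' (all trainable); batch normalization over `C` channels contributes `2C`
#' trainable (scale, shift) and `2C` non-trainable (running mean, running
#' variance) parameters; activations, pooling, concatenation and global
#' average pooling contribute nothing; the dense softmax head contributes
#' `c_in*classes + classes`.
#'
#' @param arch a `cdnet_architecture`.
#' @return An object of class `parameter_audit`: list with `per_layer`
#'   (tibble of `id`, `kind`, `trainable`, `non_trainable`),
#'   `trainable_total`, `non_trainable_total`, `grand_total`.
#' @export
count_parameters <- function(arch) {
  stopifnot(inherits(arch, "cdnet_architecture"))
  ch <- layer_channels(arch)
  layers <- arch$layers
  per <- purrr::map_dfr(seq_len(nrow(layers)), function(i) {
    l <- layers[i, ]
    ins <- l$inputs[[1]]
    cin <- if (length(ins)) sum(ch[ins]) else NA_integer_
    tr <- 0; ntr <- 0
    if (l$kind == "conv") {
      tr <- l$kernel_h * l$kernel_w * cin * l$filters +
        if (isTRUE(l$use_bias)) l$filters else 0L
    } else if (l$kind == "batch_norm") {
      tr <- 2L * cin
      ntr <- 2L * cin
    } else if (l$kind == "dense_softmax") {
      tr <- cin * l$filters + if (isTRUE(l$use_bias)) l$filters else 0L
    }
    tibble(id = l$id, kind = l$kind, trainable = as.numeric(tr),
           non_trainable = as.numeric(ntr))
  })
  structure(
    list(per_layer = per,
         trainable_total = sum(per$trainable),
         non_trainable_total = sum(per$non_trainable),
         grand_total = sum(per$trainable) + sum(per$non_trainable)),
    class = "parameter_audit"
  )
}

#' @export
print.parameter_audit <- function(x, ...) {
  cat("<parameter_audit>\n")
  print(dplyr::filter(x$per_layer, .data$trainable > 0 | .data$non_trainable > 0), n = Inf)
  cat(sprintf("trainable: %s  non-trainable: %s  total: %s\n",
              format(x$trainable_total, big.mark = ","),
              format(x$non_trainable_total, big.mark = ","),
              format(x$grand_total, big.mark = ",")))
  invisible(x)
}

#' @rdname count_parameters
#' @param x a `parameter_audit`.
#' @param ... unused.
#' @export
tidy.parameter_audit <- function(x, ...) x$per_layer

#' @rdname count_parameters
#' @export
glance.parameter_audit <- function(x, ...) {
  tibble(trainable = x$trainable_total,
         non_trainable = x$non_trainable_total,
         total = x$grand_total)
}

#' Trace the output shape of every layer
#'
#' Computes each layer's output shape under same-padding convolutions
#' (`ceil(H/stride)`) and valid 2x2 max-pooling. Concatenations require
#' matching spatial dimensions and add channels; global average pooling
#' collapses the spatial grid to 1x1.
#'
#' @param arch a `cdnet_architecture`.
#' @param input_shape `(height, width, channels)`; defaults to the shape the
#'   architecture was built for.
#' @return tibble with columns `id`, `kind`, `height`, `width`, `channels`.
#' @export
trace_shapes <- function(arch, input_shape = arch$input_shape) {
  stopifnot(inherits(arch, "cdnet_architecture"))
  layers <- arch$layers
  shp <- list()
  for (i in seq_len(nrow(layers))) {
    l <- layers[i, ]
    ins <- l$inputs[[1]]
    s <- switch(l$kind,
      input = input_shape,
      conv = {
        s0 <- shp[[ins]]
        c(ceiling(s0[1] / l$stride), ceiling(s0[2] / l$stride), l$filters)
      },
      max_pool = {
        s0 <- shp[[ins]]
        c(floor((s0[1] - l$kernel_h) / l$stride) + 1,
          floor((s0[2] - l$kernel_w) / l$stride) + 1, s0[3])
      },
      concat = {
        ss <- lapply(ins, function(j) shp[[j]])
        sp <- unique(lapply(ss, function(s) s[1:2]))
        if (length(sp) != 1) {
          abort(sprintf("concat '%s' joins feature maps of unequal spatial size.",
                        l$id),
                class = "braincdnet_shape_error")
        }
        c(sp[[1]], sum(vapply(ss, function(s) s[3], numeric(1))))
      },
      global_avg_pool = c(1, 1, shp[[ins]][3]),
      dense_softmax = c(1, 1, l$filters),
      shp[[ins[1]]]  # activation / batch_norm pass through
    )
    shp[[l$id]] <- s
  }
  purrr::map_dfr(seq_len(nrow(layers)), function(i) {
    s <- shp[[layers$id[i]]]
    tibble(id = layers$id[i], kind = layers$kind[i],
           height = as.integer(s[1]), width = as.integer(s[2]),
           channels = as.integer(s[3]))
  })
}

#' Reference parameter totals for the published BrainCDNet build
#'
#' The totals reported for the three-class BrainCDNet: 994,563 trainable and
#' 2,560 non-trainable parameters (997,123 in total).
#' @return named numeric vector with elements `trainable`, `non_trainable`,
#'   `total`.
#' @export
brain_cdnet_reference_counts <- function() {
  c(trainable = 994563, non_trainable = 2560, total = 997123)
}

#' Reconcile a parameter audit against the published totals
#'
#' Compares an audit with the reference totals of the three-class
#' BrainCDNet build and, layer by layer, with a reference audit (by default
#' the canonical `build_brain_cdnet(3)` graph), reporting any discrepancy.
#'
#' @param audit a `parameter_audit` (or a `cdnet_architecture`, which is
#'   audited first).
#' @param reference named vector as returned by
#'   [brain_cdnet_reference_counts()].
#' @param reference_audit audit to diff against per layer; defaults to the
#'   canonical three-class build.
#' @return An object of class `audit_reconciliation`: list with `pass`
#'   (logical), `expected`, `observed`, and `per_layer_delta` (tibble of
#'   layers whose counts differ from the reference audit).
#' @export
reconcile_parameter_counts <- function(audit,
                                       reference = brain_cdnet_reference_counts(),
                                       reference_audit = NULL) {
  if (inherits(audit, "cdnet_architecture")) audit <- count_parameters(audit)
  stopifnot(inherits(audit, "parameter_audit"))
  if (is.null(reference_audit)) {
    reference_audit <- count_parameters(build_brain_cdnet(3))
  }
  observed <- c(trainable = audit$trainable_total,
                non_trainable = audit$non_trainable_total,
                total = audit$grand_total)
  pass <- isTRUE(all(observed == reference[names(observed)]))
  delta <- dplyr::full_join(
    audit$per_layer, reference_audit$per_layer,
    by = "id", suffix = c("", "_ref")
  )
  delta[is.na(delta)] <- 0
  delta <- dplyr::mutate(delta,
    delta_trainable = .data$trainable - .data$trainable_ref,
    delta_non_trainable = .data$non_trainable - .data$non_trainable_ref)
  delta <- dplyr::filter(delta, .data$delta_trainable != 0 |
                                .data$delta_non_trainable != 0)
  structure(
    list(pass = pass, expected = reference, observed = observed,
         per_layer_delta = dplyr::select(delta, "id", "delta_trainable",
                                         "delta_non_trainable")),
    class = "audit_reconciliation"
  )
}

#' @export
print.audit_reconciliation <- function(x, ...) {
  cat(sprintf("<audit_reconciliation> %s\n", if (x$pass) "PASS" else "FAIL"))
  m <- rbind(expected = x$expected[c("trainable", "non_trainable", "total")],
             observed = x$observed)
  print(m)
  if (nrow(x$per_layer_delta)) {
    cat("per-layer discrepancies:\n")
    print(x$per_layer_delta, n = Inf)
  }
  invisible(x)
}
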