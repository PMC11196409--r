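test_that("per-layer parameter counts follow the standard conventions", {
  audit <- count_parameters(build_brain_cdnet(3))
  per <- audit$per_layer
  row <- function(id) per[per$id == id, ]
  # 3x3 conv, 3 in, 64 out, biased: 3*3*3*64 + 64
  expect_equal(row("a1_conv")$trainable, 1792)
  # batch norm over 64 channels: 2 trainable + 2 non-trainable per channel
  expect_equal(row("a1_bn")$trainable, 128)
  expect_equal(row("a1_bn")$non_trainable, 128)
  # parameter-free layers
  expect_equal(row("gap")$trainable, 0)
  expect_equal(row("concat_b")$trainable, 0)
  expect_equal(row("a1_pool")$trainable, 0)
  # dense softmax head: 256*3 + 3
  expect_equal(row("head")$trainable, 771)
})

test_that("the three-class build reconciles exactly with the published totals", {
  audit <- count_parameters(build_brain_cdnet(3))
  expect_identical(audit$trainable_total, 994563)
  expect_identical(audit$non_trainable_total, 2560)
  expect_identical(audit$grand_total, 997123)
  rec <- reconcile_parameter_counts(audit)
  expect_true(rec$pass)
  expect_equal(nrow(rec$per_layer_delta), 0L)
})

test_that("non-trainable parameters decompose over the ten batch-norm layers", {
  per <- count_parameters(build_brain_cdnet(3))$per_layer
  bn <- per[per$kind == "batch_norm", ]
  expect_equal(nrow(bn), 10L)
  # block-wise: 4 x 64-channel, 4 x 128-channel, 2 x 256-channel layers
  expect_equal(sum(bn$non_trainable[grepl("^a", bn$id)]), 2 * 4 * 64)
  expect_equal(sum(bn$non_trainable[grepl("^b", bn$id)]), 2 * 2 * (128 + 128))
  expect_equal(sum(bn$non_trainable[grepl("^c", bn$id)]), 2 * (256 + 256))
  expect_equal(sum(bn$non_trainable), 2560)
})

test_that("each extra class costs exactly 257 trainable parameters", {
  totals <- vapply(2:6, function(k) {
    count_parameters(build_brain_cdnet(k))$trainable_total
  }, numeric(1))
  expect_equal(diff(totals), rep(257, 4))
  expect_equal(totals[1], 994306)  # 994563 - 771 + 514
})

test_that("shape tracing reproduces the 224 -> 112 -> 56 -> 28 spatial walk", {
  arch <- build_brain_cdnet(3)
  tr <- trace_shapes(arch)
  shape <- function(id) unlist(tr[tr$id == id, c("height", "width", "channels")],
                               use.names = FALSE)
  expect_equal(shape("a1_conv"), c(112, 112, 64))
  expect_equal(shape("a1_pool"), c(56, 56, 64))
  expect_equal(shape("concat_top"), c(56, 56, 128))
  expect_equal(shape("b1_conv3"), c(56, 56, 128))
  expect_equal(shape("b1_pool"), c(28, 28, 128))
  expect_equal(shape("concat_b"), c(28, 28, 256))
  expect_equal(shape("c_conv1"), c(28, 28, 256))
  expect_equal(shape("gap"), c(1, 1, 256))
  expect_equal(shape("head"), c(1, 1, 3))
})

test_that("every concatenation conserves channels", {
  arch <- build_brain_cdnet(3)
  tr <- trace_shapes(arch)
  ch <- setNames(tr$channels, tr$id)
  concats <- arch$layers[arch$layers$kind == "concat", ]
  for (i in seq_len(nrow(concats))) {
    ins <- concats$inputs[[i]]
    expect_equal(ch[[concats$id[i]]], sum(ch[ins]))
  }
})

test_that("removing conv biases breaks reconciliation by the summed bias count", {
  arch <- build_brain_cdnet(3)
  arch$layers$use_bias[arch$layers$kind == "conv"] <- FALSE
  audit <- count_parameters(arch)
  rec <- reconcile_parameter_counts(audit)
  expect_false(rec$pass)
  # conv biases: 4*64 (block 1) + 4*128 (block 2) + 2*256 (block 3)
  expect_equal(unname(rec$expected["trainable"] - rec$observed["trainable"]),
               1280)
  expect_equal(sum(rec$per_layer_delta$delta_trainable), -1280)
})

test_that("the binary head fails reconciliation by the head difference", {
  rec <- reconcile_parameter_counts(count_parameters(build_brain_cdnet(2)))
  expect_false(rec$pass)
  head_delta <- rec$per_layer_delta[rec$per_layer_delta$id == "head", ]
  expect_equal(head_delta$delta_trainable, -257)
})

test_that("invalid class counts are rejected", {
  expect_error(build_brain_cdnet(1), class = "braincdnet_parameter_error")
})
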