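# Numerical checks of the convolutional training engine against
# independent oracles, run in double precision at desk scale.

cdnet_create <- braincdnet:::cdnet_create
cdnet_set_weights <- braincdnet:::cdnet_set_weights
cdnet_get_weights <- braincdnet:::cdnet_get_weights
cdnet_gradients <- braincdnet:::cdnet_gradients
cdnet_loss <- braincdnet:::cdnet_loss
cdnet_shapes <- braincdnet:::cdnet_shapes
cdnet_param_counts <- braincdnet:::cdnet_param_counts
he_normal_weights <- braincdnet:::he_normal_weights

test_that("the convolution primitive matches a naive sliding-window oracle", {
  set.seed(61)
  cases <- list(list(h = 6, w = 7, cin = 2, k = 3, cout = 4, stride = 1),
                list(h = 8, w = 8, cin = 3, k = 3, cout = 2, stride = 2),
                list(h = 5, w = 5, cin = 4, k = 1, cout = 3, stride = 1))
  for (cs in cases) {
    x <- array(rnorm(cs$h * cs$w * cs$cin), c(cs$h, cs$w, cs$cin))
    w <- array(rnorm(cs$k * cs$k * cs$cin * cs$cout),
               c(cs$k, cs$k, cs$cin, cs$cout))
    b <- rnorm(cs$cout)
    got <- braincdnet:::nn_conv2d(x, w, b, cs$stride)
    want <- conv_oracle(x, w, b, cs$stride)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("activations match their closed forms", {
  x <- c(-2, -0.5, 0, 0.5, 2)
  lambda <- 1.0507009873554805
  alpha <- 1.6732632423543772
  selu_ref <- ifelse(x > 0, lambda * x, lambda * alpha * (exp(x) - 1))
  expect_equal(braincdnet:::nn_selu(x), selu_ref, tolerance = 1e-12)
  gelu_ref <- x * pnorm(x)  # 0.5 x (1 + erf(x / sqrt(2)))
  expect_equal(braincdnet:::nn_gelu(x), gelu_ref, tolerance = 1e-12)
})

test_that("max pooling keeps the largest value of each 2x2 window", {
  x <- array(0, c(4, 4, 1))
  x[, , 1] <- matrix(1:16, 4, 4)
  out <- braincdnet:::nn_maxpool2(x)
  expect_equal(out[, , 1], matrix(c(6, 8, 14, 16), 2, 2))
})

test_that("training-mode batch norm standardizes with batch statistics", {
  set.seed(17)
  x <- array(rnorm(20 * 3 * 4, mean = 2, sd = 3), c(20, 3, 4))
  gamma <- c(1, 2, 0.5); beta <- c(0, 1, -1)
  out <- braincdnet:::nn_batchnorm_train(x, gamma, beta, eps = 1e-3)
  for (c in 1:3) {
    v <- as.numeric(x[, c, ])
    m <- mean(v)
    va <- mean((v - m)^2)  # biased variance
    expect_equal(out$mean[c], m, tolerance = 1e-9)
    expect_equal(out$var[c], va, tolerance = 1e-8)
    want <- gamma[c] * (x[, c, ] - m) / sqrt(va + 1e-3) + beta[c]
    expect_equal(out$y[, c, ], want, tolerance = 1e-9)
  }
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(42)
  side <- 8; B <- 3; C <- 2
  ptr <- cdnet_create(C, side, TRUE)
  w <- he_normal_weights(C)
  cdnet_set_weights(ptr, w)
  x <- array(runif(side * side * 3 * B), c(side, side, 3, B))
  y <- c(0L, 1L, 1L)
  g <- cdnet_gradients(ptr, x, y)
  h <- 1e-5
  tensors <- c("a1_conv.W", "a3_conv.b", "a2_bn.gamma", "b1_conv3.W",
               "b2_conv1.W", "b1_bn2.beta", "c_conv3.W", "c_bn1.gamma",
               "head.W", "head.b")
  for (nm in tensors) {
    v <- w[[nm]]
    for (i in sample(length(v), min(3, length(v)))) {
      wp <- w; wp[[nm]][i] <- v[i] + h
      cdnet_set_weights(ptr, wp)
      lp <- cdnet_loss(ptr, x, y)
      wm <- w; wm[[nm]][i] <- v[i] - h
      cdnet_set_weights(ptr, wm)
      lm <- cdnet_loss(ptr, x, y)
      fd <- (lp - lm) / (2 * h)
      an <- g$gradients[[nm]][i]
      expect_equal(an, fd, tolerance = 1e-4,
                   label = sprintf("analytic gradient of %s[%d]", nm, i))
    }
  }
})

test_that("materialized layer shapes match the declarative trace", {
  for (side in c(224L, 32L)) {
    arch <- build_brain_cdnet(3, input_side = side)
    tr <- trace_shapes(arch)
    ptr <- cdnet_create(3L, side, FALSE)
    shp <- cdnet_shapes(ptr)
    for (id in names(shp)) {
      want <- unlist(tr[tr$id == id, c("height", "width", "channels")],
                     use.names = FALSE)
      expect_equal(shp[[id]], want, label = sprintf("shape of %s", id))
    }
  }
})

test_that("the engine's materialized parameter count equals the audit", {
  for (C in c(2L, 3L)) {
    audit <- count_parameters(build_brain_cdnet(C))
    ptr <- cdnet_create(C, 224L, FALSE)
    counts <- cdnet_param_counts(ptr)
    expect_equal(counts$trainable, audit$trainable_total)
    expect_equal(counts$non_trainable, audit$non_trainable_total)
  }
})

test_that("weights survive a set/get round trip", {
  set.seed(3)
  w <- he_normal_weights(3)
  ptr <- cdnet_create(3L, 32L, TRUE)
  cdnet_set_weights(ptr, w)
  back <- cdnet_get_weights(ptr)
  for (nm in names(w)) {
    expect_equal(back[[nm]], w[[nm]], tolerance = 1e-12,
                 ignore_attr = TRUE, label = nm)
  }
})
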