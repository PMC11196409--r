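test_that("phantom generation is deterministic and order-independent", {
  spec <- small_phantom_spec(3, seed = 9)
  a <- generate_phantom(1, spec, 2)
  b <- generate_phantom(1, spec, 2)
  expect_identical(a, b)
  # drawing another image first must not change a given draw
  invisible(generate_phantom(0, spec, 1))
  expect_identical(generate_phantom(1, spec, 2), a)
  # different draws and different seeds differ
  expect_false(identical(generate_phantom(1, spec, 3), a))
  spec2 <- small_phantom_spec(3, seed = 10)
  expect_false(identical(generate_phantom(1, spec2, 2), a))
})

test_that("datasets are balanced and reproducible", {
  spec <- small_phantom_spec(10, n_classes = 3, seed = 4)
  ds <- generate_dataset(spec)
  expect_length(ds$images, 30L)
  expect_equal(unname(table(ds$labels)), rep(10L, 3), ignore_attr = TRUE)
  expect_equal(ds$class_names, c("glioma", "meningioma", "pituitary"))
  ds2 <- generate_dataset(spec)
  expect_identical(ds$images, ds2$images)
})

test_that("healthy phantoms have no lesion hot spot", {
  spec <- phantom_spec(1, n_classes = 2, image_side = 64, noise_sd = 0, seed = 5)
  healthy <- generate_phantom(0, spec, 1)
  expect_equal(max(healthy), 120)     # brightest pixel is the bare ellipse
  sick <- generate_phantom(1, spec, 1)
  expect_equal(max(sick), 200)        # ellipse + 80 lesion contrast
})

test_that("lesion contrast concentrates at the class intensity", {
  spec <- phantom_spec(1, n_classes = 2, image_side = 128, noise_sd = 5,
                       seed = 31)
  noiseless <- phantom_spec(1, n_classes = 2, image_side = 128, noise_sd = 0,
                            seed = 31)
  img <- generate_phantom(1, spec, 1)
  clean <- generate_phantom(1, noiseless, 1)
  lesion <- clean == 200            # lesion disc from the noise-free twin
  area <- sum(lesion)
  expect_gt(area, 20)
  observed <- mean(img[lesion]) - 120
  expect_lt(abs(observed - 80), 3 * 5 / sqrt(area))
})

test_that("a trivial intensity baseline separates the default classes", {
  # brightest-pixel summary per image; nearest-class-mean classification
  brightest <- function(img, k = 50) mean(sort(img, decreasing = TRUE)[1:k])
  for (noise in c(0, 5)) {
    spec <- phantom_spec(12, n_classes = 3, image_side = 64,
                         noise_sd = noise, seed = 77)
    ds <- generate_dataset(spec)
    feat <- vapply(ds$images, brightest, numeric(1))
    train <- seq_along(feat) %% 2 == 0
    centroids <- tapply(feat[train], ds$labels[train], mean)
    pred <- as.integer(names(centroids))[
      apply(abs(outer(feat[!train], centroids, "-")), 1, which.min)]
    acc <- mean(pred == ds$labels[!train])
    if (noise == 0) expect_equal(acc, 1) else expect_gte(acc, 0.95)
  }
})

test_that("spec validation enforces separability and ranges", {
  expect_error(phantom_spec(5, n_classes = 4), class = "braincdnet_input_error")
  expect_error(phantom_spec(0), class = "braincdnet_input_error")
  expect_error(phantom_spec(5, lesion_intensity = c(0, 10), noise_sd = 5),
               class = "braincdnet_input_error")
  spec <- small_phantom_spec(2)
  expect_error(generate_phantom(5, spec, 1), class = "braincdnet_input_error")
})
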