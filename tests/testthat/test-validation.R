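test_that("k-fold plans partition the samples exactly", {
  set.seed(1)
  for (rep in 1:5) {
    n <- sample(40:120, 1)
    labels <- sample(letters[1:3], n, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
    while (min(table(labels)) < 5) labels <- sample(letters[1:3], n, TRUE)
    plan <- kfold_split(labels, k = 5, seed = rep)
    expect_setequal(plan$index, seq_len(n))
    expect_equal(anyDuplicated(plan$index), 0L)
    expect_setequal(unique(plan$fold), 1:5)
    # stratification: per-class fold sizes differ by at most 1
    spread <- tapply(plan$fold, plan$class, function(f) {
      sizes <- tabulate(f, 5)
      max(sizes) - min(sizes)
    })
    expect_true(all(spread <= 1))
  }
})

test_that("balanced binary 100-sample 5-fold yields 20-sample folds, 10 per class", {
  labels <- rep(c("a", "b"), each = 50)
  plan <- kfold_split(labels, k = 5, seed = 3)
  expect_equal(unname(tabulate(plan$fold, 5)), rep(20L, 5))
  per_class <- table(plan$class, plan$fold)
  expect_true(all(per_class == 10))
})

test_that("103 samples split 5 ways into folds of 20 or 21", {
  labels <- rep("a", 103)
  plan <- kfold_split(labels, k = 5, seed = 2)
  expect_setequal(unique(tabulate(plan$fold, 5)), c(20L, 21L))
})

test_that("split plans are deterministic in the seed", {
  labels <- sample(c("x", "y"), 60, replace = TRUE)
  p1 <- kfold_split(labels, k = 5, seed = 7)
  p2 <- kfold_split(labels, k = 5, seed = 7)
  expect_identical(p1$fold, p2$fold)
  p3 <- kfold_split(labels, k = 5, seed = 8)
  expect_false(identical(p1$fold, p3$fold))

  h1 <- holdout_split(labels, 0.75, seed = 7)
  h2 <- holdout_split(labels, 0.75, seed = 7)
  expect_identical(h1$partition, h2$partition)
})

test_that("holdout splits stratify with per-class round-half-up counts", {
  labels <- rep(c("a", "b"), each = 100)
  plan <- holdout_split(labels, 0.75, seed = 1)
  expect_equal(sum(plan$partition == "train"), 150L)
  expect_equal(sum(plan$partition == "test"), 50L)
  tab <- table(plan$class, plan$partition)
  expect_true(all(tab[, "train"] == 75))

  plan85 <- holdout_split(labels, 0.85, seed = 1)
  expect_equal(sum(plan85$partition == "train"), 170L)
  expect_equal(sum(plan85$partition == "test"), 30L)

  # per-class rounding: 60 * .85 = 51, 41 * .85 = 34.85 -> 35
  mixed <- holdout_split(rep(c("a", "b"), times = c(60, 41)), 0.85, seed = 2)
  expect_equal(sum(mixed$partition == "train"), 86L)
  tabm <- table(mixed$class, mixed$partition)
  expect_equal(unname(tabm["a", "train"]), 51L)
  expect_equal(unname(tabm["b", "train"]), 35L)
})

test_that("degenerate splits raise stratification errors", {
  expect_error(kfold_split(c(rep("a", 10), rep("b", 3)), k = 5, seed = 1),
               class = "braincdnet_stratification_error")
  expect_error(holdout_split(rep(c("a", "b"), c(50, 1)), 0.9, seed = 1),
               class = "braincdnet_stratification_error")
  expect_error(holdout_split(rep("a", 10), 1.2, seed = 1),
               class = "braincdnet_parameter_error")
})

test_that("cross-fold aggregation is the arithmetic mean per metric", {
  r <- tibble::tibble(class = c("a", "b"), tpr = c(90, 80), accuracy = c(85, 95))
  expect_equal(aggregate_cv_metrics(list(r, r, r)), r)

  r2 <- r
  r2$tpr <- c(100, 90); r2$accuracy <- c(95, 85)
  agg <- aggregate_cv_metrics(list(r, r2))
  expect_equal(agg$tpr, c(95, 85))
  expect_equal(agg$accuracy, c(90, 90))

  accs <- c(99.0, 99.5, 99.5, 99.5, 99.7)
  reports <- lapply(accs, function(a) tibble::tibble(accuracy = a))
  expect_equal(aggregate_cv_metrics(reports)$accuracy, 99.44)

  bad <- tibble::tibble(class = c("a", "b"), tnr = c(1, 2), accuracy = c(3, 4))
  expect_error(aggregate_cv_metrics(list(r, bad)),
               class = "braincdnet_aggregation_error")
})
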