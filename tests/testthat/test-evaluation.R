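test_that("confusion matrices tally label pairs", {
  cm <- confusion_matrix(rep(0:1, each = 50), rep(0:1, each = 50), 2)
  expect_equal(unclass(cm), diag(c(50L, 50L)), ignore_attr = TRUE)

  flipped <- confusion_matrix(rep(0:1, each = 4), rep(1:0, each = 4), 2)
  expect_equal(diag(flipped), c(0L, 0L))
  expect_equal(flipped[1, 2], 4L)

  cm3 <- confusion_matrix(c(0, 0, 1, 1, 2), c(0, 1, 1, 1, 2), 3)
  expect_equal(cm3[1, 1], 1L)
  expect_equal(cm3[1, 2], 1L)
  expect_equal(cm3[2, 2], 2L)
  expect_equal(cm3[3, 3], 1L)
  expect_equal(sum(cm3), 5L)

  expect_error(confusion_matrix(c(0, 3), c(0, 1), 2),
               class = "braincdnet_input_error")
})

test_that("binary metrics match hand-evaluated formulas", {
  perfect <- matrix(c(50, 0, 0, 50), 2, 2)
  m <- binary_metrics(perfect)
  expect_equal(unlist(m), c(tpr = 100, tnr = 100, ppv = 100,
                            f_score = 100, accuracy = 100))

  # TP=90 FN=10 TN=80 FP=20 (rows true, cols predicted, class 2 positive)
  cm <- matrix(c(80, 10, 20, 90), 2, 2)
  m2 <- binary_metrics(cm)
  expect_equal(m2$tpr, 90)
  expect_equal(m2$tnr, 80)
  expect_equal(m2$ppv, 81.82, tolerance = 1e-4)
  expect_equal(m2$f_score, 85.71, tolerance = 1e-4)
  expect_equal(m2$accuracy, 85)
})

test_that("metrics with empty denominators are undefined, not zero", {
  no_pos <- matrix(c(10, 0, 5, 0), 2, 2)  # no true positives exist
  m <- binary_metrics(no_pos)
  expect_true(is.na(m$tpr))
  expect_false(isTRUE(m$tpr == 0))
})

test_that("one-vs-rest reduction reproduces hand-tallied per-class metrics", {
  # count matrix [[8,1,1],[0,9,1],[1,0,9]] expressed as label vectors
  truth <- rep(0:2, each = 10)
  pred <- c(rep(0, 8), 1, 2,
            rep(1, 9), 2,
            0, rep(2, 9))
  cm <- confusion_matrix(truth, pred, 3)
  expect_equal(unclass(cm),
               matrix(c(8, 1, 1, 0, 9, 1, 1, 0, 9), 3, 3, byrow = TRUE),
               ignore_attr = TRUE)
  rep3 <- per_class_metrics_ovr(cm)
  c0 <- rep3[rep3$class == "class_0", ]
  expect_equal(c0$tpr, 80)
  expect_equal(c0$ppv, 800 / 9, tolerance = 1e-9)
  expect_equal(attr(rep3, "overall_accuracy"), 100 * 26 / 30)
  # macro row is the arithmetic mean and lies within per-class extremes
  per <- rep3[rep3$class != "macro", ]
  macro <- rep3[rep3$class == "macro", ]
  for (col in c("tpr", "tnr", "ppv", "f_score", "accuracy")) {
    expect_equal(macro[[col]], mean(per[[col]]))
    expect_gte(macro[[col]], min(per[[col]]))
    expect_lte(macro[[col]], max(per[[col]]))
  }
})

test_that("macro averaging reproduces the published multiclass average row", {
  # published 5-fold CV per-class sensitivities and their printed average
  expect_equal(round(mean(c(93.20, 99.32, 88.12)), 2), 93.55)
  cmwise <- tibble::tibble(class = c("glioma", "meningioma", "pituitary"),
                           tpr = c(93.20, 99.32, 88.12))
  agg <- dplyr::summarise(cmwise, tpr = mean(tpr))
  expect_equal(round(agg$tpr, 2), 93.55)
})

test_that("overall accuracy is invariant to class relabelling", {
  set.seed(13)
  truth <- sample(0:2, 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(0:2, 60, replace = TRUE))
  cm <- confusion_matrix(truth, pred, 3)
  perm <- c(2L, 0L, 1L)
  cmp <- confusion_matrix(perm[truth + 1], perm[pred + 1], 3)
  expect_equal(attr(per_class_metrics_ovr(cm), "overall_accuracy"),
               attr(per_class_metrics_ovr(cmp), "overall_accuracy"))
})

test_that("AUC equals the pairwise Mann-Whitney statistic", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3), 1), 0.75)
  # perfect separation and pure ties
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), 1), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4), 1), 0.5)

  set.seed(101)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    score <- round(runif(n), 2)  # rounding forces occasional ties
    expect_equal(roc_auc(truth, score, 1),
                 auc_bruteforce(truth, score, 1))
  }
})

test_that("AUC agrees with an established implementation", {
  set.seed(55)
  truth <- sample(0:1, 40, replace = TRUE)
  truth[1:2] <- 0:1
  score <- runif(40)
  got <- roc_auc(truth, score, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("AUC flips with the labels in the absence of ties", {
  set.seed(77)
  truth <- c(0, 1, sample(0:1, 10, replace = TRUE))
  score <- runif(12)
  expect_equal(roc_auc(truth, score, 1) + roc_auc(1 - truth, score, 1), 1)
})

test_that("ROC curves are monotone and their trapezoidal area equals the AUC", {
  set.seed(303)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    score <- round(runif(n), 1)
    curve <- roc_curve(truth, score, 1)
    expect_equal(curve$fpr[1], 0); expect_equal(curve$tpr[1], 0)
    expect_equal(curve$fpr[nrow(curve)], 1)
    expect_equal(curve$tpr[nrow(curve)], 1)
    expect_true(all(diff(curve$fpr) >= 0))
    expect_true(all(diff(curve$tpr) >= 0))
    expect_equal(auc_trapezoid(curve), roc_auc(truth, score, 1))
  }
  # perfect separation passes through (0, 1)
  perf <- roc_curve(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), 1)
  expect_true(any(perf$fpr == 0 & perf$tpr == 1))
  expect_equal(auc_trapezoid(roc_curve(c(1, 0, 1, 0),
                                       c(0.9, 0.8, 0.4, 0.3), 1)), 0.75)
})

test_that("single-class score sets are rejected", {
  expect_error(roc_auc(c(1, 1, 1), c(0.1, 0.5, 0.9), 1),
               class = "braincdnet_input_error")
})

test_that("multiclass AUC is one-vs-rest per class", {
  set.seed(21)
  truth <- sample(0:2, 30, replace = TRUE)
  scores <- matrix(runif(90), 30, 3)
  scores <- scores / rowSums(scores)
  out <- multiclass_auc(truth, scores)
  expect_equal(nrow(out), 3L)
  for (c in 0:2) {
    expect_equal(out$auc[out$class_index == c],
                 auc_bruteforce(as.integer(truth == c), scores[, c + 1], 1))
  }
})
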