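test_that("stratified split reproduces the 80/20 count arithmetic", {
  labels <- rep(c("CTC", "non-CTC"), c(694, 13472))
  sp <- split_spec(test_fraction = 0.2, seed = 4)
  s <- stratified_split(labels, sp)
  expect_equal(sum(labels[s$test] == "CTC"), 139)
  expect_equal(sum(labels[s$test] == "non-CTC"), 2695)
  expect_equal(sum(labels[s$train] == "CTC"), 555)
  expect_equal(sum(labels[s$train] == "non-CTC"), 10777)
  # conservation and disjointness
  expect_setequal(c(s$train, s$test), seq_along(labels))
  expect_length(intersect(s$train, s$test), 0)
  # determinism
  s2 <- stratified_split(labels, sp)
  expect_identical(s, s2)
})

test_that("split handles exact fractions and empty-train errors", {
  labels <- rep(c("a", "b"), each = 10)
  s <- stratified_split(labels, split_spec(test_fraction = 0.5, seed = 1))
  expect_equal(unname(s$per_class_test_counts), c(5L, 5L))
  expect_error(stratified_split(c("a", "a", "b"),
                                split_spec(test_fraction = 0.9, seed = 1)),
               "empty training partition")
})

test_that("down-sampling balances to twice the minority count", {
  labels <- rep(c(1, 0), c(555, 10777))
  keep <- downsample_majority(labels, seed = 2)
  expect_length(keep, 1110)
  expect_equal(sum(labels[keep] == 1), 555)
  expect_equal(sum(labels[keep] == 0), 555)
  # balanced input is a fixed point (as a set)
  bal <- rep(c(1, 0), each = 7)
  expect_setequal(downsample_majority(bal, seed = 3), seq_along(bal))
  # seed changes membership, never counts
  k2 <- downsample_majority(labels, seed = 9)
  expect_length(k2, 1110)
  expect_false(identical(keep, k2))
})

test_that("AUC equals the brute-force Mann-Whitney pair statistic", {
  mw <- function(scores, y) {
    pos <- scores[y == 1]; neg <- scores[y == 0]
    pr <- outer(pos, neg, ">"); ti <- outer(pos, neg, "==")
    (sum(pr) + 0.5 * sum(ti)) / (length(pos) * length(neg))
  }
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:200, 1)
    y <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))
    scores <- if (rep %% 3 == 0) sample(0:5, n, replace = TRUE) / 5 else stats::runif(n)
    r <- roc_auc(scores, y)
    expect_equal(r$auc, mw(scores, y), tolerance = 1e-12)
    # ROC invariants: endpoints and monotone coordinates
    expect_equal(r$roc_points$fpr[1], 0)
    expect_equal(r$roc_points$tpr[1], 0)
    expect_equal(r$roc_points$fpr[nrow(r$roc_points)], 1)
    expect_equal(r$roc_points$tpr[nrow(r$roc_points)], 1)
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- stats::rbinom(300, 1, 0.3)
  s <- stats::runif(300) + 0.4 * y
  ours <- roc_auc(s, y)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("perfect separation gives AUC 1 and label-independent scores give ~0.5", {
  y <- rep(c(1, 0), each = 20)
  expect_equal(roc_auc(rep(c(1, 0), each = 20), y)$auc, 1)
  set.seed(12)
  n <- 4000
  y2 <- stats::rbinom(n, 1, 0.5)
  s2 <- stats::runif(n)
  null_sd <- sqrt((n + 1) / (12 * sum(y2 == 1) * sum(y2 == 0)))
  expect_lt(abs(roc_auc(s2, y2)$auc - 0.5), 3 * null_sd)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("confusion statistics follow their definitions", {
  expect_equal(confusion_stats(c(1, 0, 1), c(1, 0, 1))$sensitivity, 1)
  expect_equal(confusion_stats(c(1, 0, 1), c(1, 0, 1))$specificity, 1)
  inv <- confusion_stats(c(0, 1, 0), c(1, 0, 1))
  expect_equal(inv$sensitivity, 0)
  expect_equal(inv$specificity, 0)
  pred <- rep(c(1, 0, 0, 1), c(35, 2, 50, 5))
  truth <- rep(c(1, 1, 0, 0), c(35, 2, 50, 5))
  r <- confusion_stats(pred, truth)
  expect_equal(r$tp, 35); expect_equal(r$fn, 2)
  expect_equal(r$tn, 50); expect_equal(r$fp, 5)
  expect_equal(r$sensitivity, 35 / 37)
  expect_equal(r$specificity, 50 / 55)
  expect_error(confusion_stats(c(1, 0), c(1, 0, 1)), "lengths differ")
})

test_that("k-fold CV partitions are disjoint, exhaustive, and stratified", {
  labels <- rep(c(1, 0), each = 50)
  res <- kfold_cv(seq_along(labels), labels, k = 5, seed = 3,
                  train_fn = function(idx, y) y,
                  predict_fn = function(fit, idx) as.numeric(labels[idx]))
  expect_equal(sort(unique(res$fold)), 1:5)
  expect_equal(as.vector(table(res$fold)), rep(20, 5))
  # stratification within 1 item per class
  for (f in 1:5) {
    expect_lte(abs(sum(labels[res$fold == f] == 1) - 10), 1)
  }
  # a perfect oracle predictor is perfect in every fold
  for (r in res$per_fold) {
    expect_equal(r$sensitivity, 1)
    expect_equal(r$specificity, 1)
  }
  expect_equal(res$pooled$auc, 1)
  expect_error(kfold_cv(1:6, c(1, 1, 1, 0, 0, 0), k = 5, seed = 1,
                        function(i, y) y, function(f, i) 1),
               "fewer members")
})
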