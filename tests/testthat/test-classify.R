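test_that("feature matrices have the contracted shapes and round-trip", {
  f <- classif_fixture(3)
  expect_equal(ncol(f$connection), 10 * 9 / 2)
  expect_equal(ncol(f$nodal), 3 * 10)
  set.seed(1)
  m <- matrix(rnorm(36), 6, 6); m <- (m + t(m)) / 2; diag(m) <- 0
  expect_equal(unvec_upper(vec_upper(m)), unname(m))
})

test_that("t-test selection honours alpha, skips constants, never leaks", {
  set.seed(3)
  n <- 60
  x <- cbind(strong = c(rnorm(30), rnorm(30) + 5),
             noise = rnorm(n),
             flat = rep(1, n))
  y <- rep(c("A", "B"), each = 30)
  mask <- select_features(x, y, alpha = 0.001)
  expect_true(mask[1])
  expect_false(mask[3])
  expect_false(attr(mask, "fallback"))
  # p-values agree with t.test
  p <- attr(mask, "p_values")
  expect_equal(unname(p[1]), t.test(x[1:30, 1], x[31:60, 1],
                            var.equal = TRUE)$p.value, tolerance = 1e-12)
  # leakage contract: the mask from a training subset ignores other rows
  tr <- 1:40
  m1 <- select_features(x[tr, ], y[tr], 0.001)
  x2 <- x; x2[41:60, ] <- 1e6
  m2 <- select_features(x2[tr, ], y[tr], 0.001)
  expect_identical(as.logical(m1), as.logical(m2))
  # empty selection falls back to the single best feature
  xw <- cbind(a = rnorm(n), b = rnorm(n))
  mw <- select_features(xw, y, alpha = 1e-12)
  expect_true(attr(mw, "fallback"))
  expect_equal(sum(mw), 1)
})

test_that("confusion metrics follow the exact formulas", {
  # TP=3, TN=4, FP=1, FN=2
  labels <- c(rep("B", 5), rep("A", 5))
  preds <- c("B", "B", "B", "A", "A", "A", "A", "A", "A", "B")
  cm <- confusion_metrics(preds, labels)
  expect_equal(cm[c("tp", "tn", "fp", "fn")], list(tp = 3, tn = 4, fp = 1, fn = 2))
  expect_equal(cm$accuracy, 0.7)
  expect_equal(cm$sensitivity, 0.6)
  expect_equal(cm$specificity, 0.8)
  all_right <- confusion_metrics(labels, labels)
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
  none <- confusion_metrics(rep("A", 10), labels)
  expect_equal(none$sensitivity, 0)
})

test_that("ROC/AUC matches the concordance oracle, including ties", {
  expect_equal(roc_auc(1:4, c("A", "A", "B", "B"))$auc, 1)
  expect_equal(roc_auc(4:1, c("A", "A", "B", "B"))$auc, 0)
  set.seed(4)
  for (rep in 1:5) {
    scores <- sample(seq(0, 1, 0.1), 20, replace = TRUE)  # forces ties
    labels <- sample(rep(c("A", "B"), 10))
    got <- roc_auc(scores, labels)$auc
    expect_equal(got, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(got, as.numeric(suppressMessages(
      pROC::auc(pROC::roc(labels, scores, levels = c("A", "B"),
                          direction = "<")))), tolerance = 1e-12)
  }
  deg <- roc_auc(rep(0.3, 8), rep(c("A", "B"), 4))
  expect_equal(deg$auc, 0.5)
  expect_true(deg$degenerate)
  set.seed(5)
  big <- roc_auc(rnorm(2000), sample(rep(c("A", "B"), 1000)))
  expect_gt(big$auc, 0.45)
  expect_lt(big$auc, 0.55)
})

test_that("forced kernel weights reproduce the single-family classifier", {
  f <- classif_fixture(6, shift = 0.4, seed = 6)
  conn_only <- mkl_svm_loocv(f, families = "connection", seed = 7)
  forced <- mkl_svm_loocv(f, beta = c(1, 0), seed = 7)
  expect_identical(forced$fold_predictions$prediction,
                   conn_only$fold_predictions$prediction)
  expect_equal(forced$fold_predictions$score,
               conn_only$fold_predictions$score, tolerance = 1e-8)
  nodal_only <- mkl_svm_loocv(f, families = "nodal", seed = 7)
  forced2 <- mkl_svm_loocv(f, beta = c(0, 1), seed = 7)
  expect_identical(forced2$fold_predictions$prediction,
                   nodal_only$fold_predictions$prediction)
})

test_that("LOOCV accuracy rises with the planted effect size", {
  accs <- vapply(c(0, 0.15, 0.3), function(shift) {
    med <- vapply(1:3, function(s) {
      f <- classif_fixture(8, shift = shift, seed = 20 + s, noise = 0.15)
      mkl_svm_loocv(f, beta = c(0.5, 0.5), seed = 30 + s)$accuracy
    }, numeric(1))
    median(med)
  }, numeric(1))
  expect_true(accs[1] <= accs[2] + 1e-9 && accs[2] <= accs[3] + 1e-9)
  expect_gt(accs[3], accs[1])
})

test_that("pooled selection mode and fold mode both run and report config", {
  f <- classif_fixture(5, shift = 0.5, seed = 8)
  r_fold <- mkl_svm_loocv(f, seed = 9)
  r_pool <- mkl_svm_loocv(f, selection = "pooled", seed = 9)
  expect_equal(r_fold$config$selection, "fold")
  expect_equal(r_pool$config$selection, "pooled")
  expect_true(all(r_pool$accuracy >= 0 & r_pool$accuracy <= 1))
  expect_equal(sum(unlist(r_fold$confusion)), 10)
  expect_equal(sum(r_fold$kernel_weights), 1, tolerance = 1e-9)
})
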