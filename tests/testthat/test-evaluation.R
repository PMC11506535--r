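test_that("confusion reports recompute every percentage from counts alone", {
  # occurrence counts of a 364-case binary model (rows = predicted)
  r <- confusion_report_from_counts(matrix(c(178, 33, 25, 128), 2, 2))
  expect_equal(r$reliability[1, ], c("0" = 87.6847, "1" = 12.3153),
               tolerance = 1e-4)
  expect_equal(r$reliability[2, ], c("0" = 20.4969, "1" = 79.5031),
               tolerance = 1e-4)
  expect_equal(diag(r$precision), c("0" = 84.3602, "1" = 83.6601),
               tolerance = 1e-4)
  expect_equal(r$precision[1, 2], 16.3399, tolerance = 1e-4)
  expect_equal(r$overall_precision, 84.0659, tolerance = 1e-4)
  expect_equal(r$mean_precision, 84.0102, tolerance = 1e-4)
  expect_equal(r$overall_reliability, 84.2457, tolerance = 1e-4)
  expect_equal(r$mean_reliability, 83.5939, tolerance = 1e-4)
  expect_identical(r$misclassified, 58)

  r2 <- confusion_report_from_counts(matrix(c(195, 16, 17, 136), 2, 2))
  expect_equal(r2$overall_precision, 90.9341, tolerance = 1e-4)
  expect_identical(r2$misclassified, 33)
  expect_equal(r2$reliability[1, 1], 91.9811, tolerance = 1e-4)
  expect_equal(r2$reliability[2, ], c("0" = 10.5263, "1" = 89.4737),
               tolerance = 1e-4)
  expect_equal(diag(r2$precision), c("0" = 92.4171, "1" = 88.8889),
               tolerance = 1e-4)
  expect_equal(r2$mean_precision, 90.6530, tolerance = 1e-4)
  expect_equal(r2$overall_reliability, 90.9272, tolerance = 1e-4)
  expect_equal(r2$mean_reliability, 90.7274, tolerance = 1e-4)

  # row/column normalizations always close to 100%
  expect_equal(unname(rowSums(r$reliability)), c(100, 100), tolerance = 1e-9)
  expect_equal(unname(colSums(r$precision)), c(100, 100), tolerance = 1e-9)
})

test_that("confusion report from labels matches counts and handles edge cases", {
  pred <- c(0, 0, 1, 1, 1); truth <- c(0, 1, 1, 1, 0)
  r <- confusion_report(pred, truth)
  expect_equal(unname(r$occurrences), matrix(c(1, 1, 1, 2), 2, 2))
  perfect <- confusion_report(truth, truth)
  expect_equal(perfect$overall_precision, 100)
  expect_identical(perfect$misclassified, 0)
  expect_error(confusion_report(c(0, 1), c(0, 1, 1)), "equal length")
})

test_that("AUC uses midranks and matches the all-pairs oracle", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    truth <- rbinom(n, 1, 0.4)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # induce ties sometimes
    auc <- thermotan:::auc_midrank(scores, truth)
    pos <- scores[truth == 1]; neg <- scores[truth == 0]
    conc <- 0
    for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
    expect_equal(auc, conc / (length(pos) * length(neg)), tolerance = 1e-12)
  }
})

test_that("index relations hold identically and perfect ranking saturates", {
  truth <- c(0, 0, 1, 1, 0, 1)
  ps <- performance_summary(as.numeric(truth), truth)
  expect_equal(ps$roc_index, 100)
  expect_equal(ps$gini_index, 50)
  expect_equal(ps$relative_gini, 100)

  set.seed(20)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) next
    scores <- runif(n)
    ps <- performance_summary(scores, truth)
    expect_equal(ps$roc_index, 50 + ps$gini_index, tolerance = 1e-12)
    expect_identical(ps$relative_gini, 2 * ps$gini_index)
    expect_gte(ps$calibration_index, 0)
    expect_lte(ps$calibration_index, 100)
  }

  # a large null has a ROC index near 50
  set.seed(33)
  truth <- rbinom(10000, 1, 0.42)
  ps <- performance_summary(runif(10000), truth)
  expect_lt(abs(ps$roc_index - 50), 2)
  expect_error(performance_summary(runif(5), rep(1, 5)), "one class")
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(2)
  truth <- rbinom(300, 1, 0.45)
  scores <- runif(300) + truth * 0.4
  ours <- thermotan:::auc_midrank(scores, truth)
  theirs <- as.numeric(suppressMessages(pROC::auc(truth, scores)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("the eight metrics follow their closed forms and degrade safely", {
  m <- eight_metrics(predicted = rep(c(0, 1), c(203, 161)),
                     prob = NULL,
                     truth = c(rep(0, 178), rep(1, 25), rep(0, 33), rep(1, 128)))
  expect_equal(unname(m["accuracy"]), 306 / 364, tolerance = 1e-9)
  expect_equal(unname(m["recall"]), 128 / 153, tolerance = 1e-9)
  expect_equal(unname(m["specificity"]), 178 / 211, tolerance = 1e-9)

  set.seed(11)
  for (i in 1:30) {
    truth <- rbinom(60, 1, 0.5); pred <- rbinom(60, 1, 0.5)
    m <- eight_metrics(pred, runif(60), truth)
    tp <- sum(pred & truth); tn <- sum(!pred & !truth)
    fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    if (den > 0)
      expect_equal(unname(m["mcc"]), (tp * tn - fp * fn) / den,
                   tolerance = 1e-9)
  }

  all_pos <- eight_metrics(rep(1, 10), NULL, rep(c(0, 1), 5))
  expect_equal(unname(all_pos["recall"]), 1)
  expect_equal(unname(all_pos["specificity"]), 0)
  no_pred_pos <- eight_metrics(rep(0, 10), NULL, rep(c(0, 1), 5))
  expect_true(is.na(no_pred_pos["precision"]))   # undefined, not zero
})

test_that("stratified K-fold pools exactly N out-of-fold predictions", {
  set.seed(40)
  n <- 60
  tab <- data.frame(x = c(rnorm(30, 0), rnorm(30, 8)),
                    diagnosis = rep(0:1, each = 30))
  tab <- tab[sample(n), ]
  learner <- list(
    fit = function(train) {
      c(m0 = mean(train$x[train$diagnosis == 0]),
        m1 = mean(train$x[train$diagnosis == 1]))
    },
    predict = function(model, test) {
      as.numeric(abs(test$x - model["m1"]) < abs(test$x - model["m0"]))
    })
  res <- kfold(tab, "diagnosis", K = 5, learner, seed = 2)
  expect_equal(length(res$prob), n)
  expect_equal(res$confusion$n, n)
  # class proportions preserved within 1 per fold
  for (k in 1:5) {
    yk <- tab$diagnosis[res$folds == k]
    expect_lte(abs(sum(yk == 1) - sum(yk == 0)), 1)
  }
  res2 <- kfold(tab, "diagnosis", K = 5, learner, seed = 2)
  expect_identical(res$folds, res2$folds)

  # leave-one-out on a separable dataset is essentially perfect
  loo <- kfold(tab, "diagnosis", K = n, learner, seed = 3)
  expect_gte(loo$confusion$overall_precision, 95)
})
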