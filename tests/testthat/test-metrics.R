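test_that("ROC-AUC matches hand-counted concordance", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("ROC-AUC equals the exhaustive pairwise oracle", {
  withr::with_seed(13, {
    for (i in 1:40) {
      n <- sample(4:50, 1)
      labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))
      scores <- round(stats::runif(n), sample(1:3, 1))  # force ties often
      expect_equal(roc_auc(labels, scores), auc_oracle(labels, scores))
    }
  })
})

test_that("complement symmetry holds with ties counted half", {
  withr::with_seed(17, {
    for (i in 1:10) {
      labels <- c(0, 1, stats::rbinom(20, 1, 0.5))
      scores <- round(stats::runif(22), 1)
      expect_equal(roc_auc(labels, scores) + roc_auc(labels, 1 - scores), 1)
    }
  })
})

test_that("classification metrics reproduce hand confusion counts", {
  m <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2), 0.5)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$fpr, 0.5)
  expect_equal(m$f1, 0.5)

  perfect <- classification_metrics(c(1, 1, 0), c(0.9, 0.8, 0.1), 0.5)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$f1, 2 * 1 * 1 / 2)

  # undefined precision (no positive calls) reported as 0 and flagged
  none <- classification_metrics(c(1, 0), c(0.2, 0.1), 0.5)
  expect_equal(none$precision, 0)
  expect_true(none$degenerate)
})

test_that("recall is monotone non-increasing in the cutoff", {
  withr::with_seed(19, {
    labels <- c(0, 1, stats::rbinom(40, 1, 0.5))
    scores <- stats::runif(42)
    r1 <- classification_metrics(labels, scores, 0.5)$recall
    r2 <- classification_metrics(labels, scores, 0.7)$recall
    expect_lte(r2, r1)
  })
})

test_that("best balanced-accuracy cutoff matches the exhaustive scan", {
  withr::with_seed(23, {
    for (i in 1:40) {
      n <- sample(4:40, 1)
      labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
      scores <- round(stats::runif(n), sample(1:2, 1))
      got <- best_ba_cutoff(labels, scores)
      expect_equal(got$balanced_accuracy, ba_oracle(labels, scores))
      # the returned cutoff really achieves the reported BA
      pred <- scores > got$cutoff
      ba <- (sum(pred & labels == 1) / sum(labels == 1) +
               sum(!pred & labels == 0) / sum(labels == 0)) / 2
      expect_equal(ba, got$balanced_accuracy)
    }
  })
})

test_that("separable scores reach BA 1 at the smallest qualifying cutoff", {
  got <- best_ba_cutoff(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(got$balanced_accuracy, 1)
  expect_equal(got$cutoff, 0.5)  # smallest midpoint separating the classes
})

test_that("duplicating all examples proportionally keeps the best cutoff", {
  labels <- c(1, 0, 1, 0, 1)
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6)
  a <- best_ba_cutoff(labels, scores)
  b <- best_ba_cutoff(rep(labels, 3), rep(scores, 3))
  expect_equal(a, b)
})

test_that("roc_auc agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(29, {
    labels <- c(0, 1, stats::rbinom(60, 1, 0.5))
    scores <- stats::runif(62)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(labels, scores), ref)
  })
})
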