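test_that("the tri-level call rule partitions [0, 1]", {
  lv <- activity_level(c(0.777, 0.54, 0.105))
  expect_equal(as.character(lv), c("high", "medium", "low"))
  # boundaries: thresholds are strict
  expect_equal(as.character(activity_level(c(0.5, 0.7, 0.7000001))),
               c("low", "medium", "high"))
  grid <- seq(0, 1, by = 0.01)
  lv2 <- activity_level(grid)
  expect_false(anyNA(lv2))
  expect_error(activity_level(1.2), "0, 1")
})

test_that("a separable toy problem is fit perfectly and deterministically", {
  ex <- toy_examples(30, 30, seed = 2)
  ex$L_x <- ifelse(ex$label == "active", 2, -2) + 0.1 * stats::rnorm(60)
  m1 <- fit_pcm_rf(ex, n_per_target = NULL, n_trees = 100, seed = 1)
  s1 <- predict(m1, ex)$score
  expect_equal(roc_auc(ex$label, s1), 1.0)
  expect_true(all(s1 >= 0 & s1 <= 1))

  m2 <- fit_pcm_rf(ex, n_per_target = NULL, n_trees = 100, seed = 1)
  expect_identical(s1, predict(m2, ex)$score)

  expect_error(fit_pcm_rf(dplyr::filter(ex, label == "active"),
                          n_per_target = NULL),
               "both classes")
})

test_that("fit -> augment -> predict is reproducible end to end", {
  ex <- tiny_examples()
  sp <- split_examples(ex, 0.8, seed = 21)
  m1 <- fit_pcm_rf(sp$train, n_per_target = 200, sigma = 0.1, n_trees = 60,
                   seed = 77)
  m2 <- fit_pcm_rf(sp$train, n_per_target = 200, sigma = 0.1, n_trees = 60,
                   seed = 77)
  expect_identical(predict(m1, sp$validation)$score,
                   predict(m2, sp$validation)$score)
})

test_that("models embed featurization provenance and survive a round trip", {
  sim <- tiny_sim()
  ex <- tiny_examples()
  m <- fit_pcm_rf(ex, panel = sim$panel, n_per_target = 200, sigma = 0.1,
                  n_trees = 50, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_pcm_model(m, path)
  m2 <- load_pcm_model(path)
  expect_identical(m2$feature_names, m$feature_names)
  expect_identical(predict(m2, ex[1:5, ])$score, predict(m, ex[1:5, ])$score)
  expect_equal(length(m$protein_features), 30)
  expect_equal(length(m$ligand_features), 187)
  expect_equal(m$thresholds, c(medium = 0.5, high = 0.7))
})

test_that("pair prediction preserves compound-major order", {
  sim <- tiny_sim()
  ex <- tiny_examples()
  m <- fit_pcm_rf(ex, panel = sim$panel, n_per_target = 200, sigma = 0.1,
                  n_trees = 50, seed = 1)
  cmp <- sim$compounds[1:3, ]
  tg <- sim$panel[1:2, c("id", "sequence")]
  res <- suppressMessages(predict_activity(m, cmp, tg))
  expect_equal(res$compound_id, rep(cmp$id, each = 2))
  expect_equal(res$target_id, rep(tg$id, 3))
  expect_true(all(res$score >= 0 & res$score <= 1))
  # target ids can also be given as panel member names
  res2 <- suppressMessages(predict_activity(m, cmp, tg$id))
  expect_equal(res$score, res2$score)
  expect_error(predict_activity(m, cmp, "NOT_A_TARGET"), "not in the model")
})

test_that("screening cutoff levels call positives as specified", {
  sim <- tiny_sim()
  ex <- tiny_examples()
  m <- fit_pcm_rf(ex, panel = sim$panel, n_per_target = 200, sigma = 0.1,
                  n_trees = 50, seed = 1)
  cmp <- sim$compounds[1:6, ]
  tg <- sim$panel[1:2, c("id", "sequence")]
  s1 <- suppressMessages(screen_compounds(m, cmp, tg, cutoff_level = 1))
  s2 <- suppressMessages(screen_compounds(m, cmp, tg, cutoff_level = 2))
  expect_identical(s1$positive, s1$score > 0.5)
  expect_identical(s2$positive, s2$score > 0.7)
  summ <- screen_summary(s1)
  expect_equal(summ$n_compounds, rep(6, 2))
  expect_equal(summ$prop_positive, summ$n_positive / summ$n_compounds)
  expect_error(screen_compounds(m, cmp, tg, cutoff_level = 3), "1 or 2")
})

test_that("model accessors summarise the fit", {
  sim <- tiny_sim()
  ex <- tiny_examples()
  m <- fit_pcm_rf(ex, panel = sim$panel, n_per_target = 200, sigma = 0.1,
                  n_trees = 50, seed = 1)
  td <- tidy(m)
  expect_setequal(td$feature, m$feature_names)
  expect_setequal(unique(td$block), c("protein", "ligand"))
  expect_false(is.unsorted(rev(td$importance)))
  g <- glance(m)
  expect_equal(g$n_features, 217)
  expect_equal(g$learner, "rf")
})
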