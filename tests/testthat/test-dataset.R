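test_that("EC50 dichotomization at 1 uM is boundary-inclusive and monotone", {
  expect_equal(label_from_ec50(0.012), "active")
  expect_equal(label_from_ec50(1.0), "active")
  expect_equal(label_from_ec50(50.0), "inactive")
  expect_error(label_from_ec50(0), "positive")
  expect_error(label_from_ec50(c(1, NA)), "positive|missing")
  # monotone: lower EC50 is never less active
  ec <- sort(10^stats::runif(50, -3, 2))
  lab <- label_from_ec50(ec)
  expect_false(is.unsorted(rev(as.integer(lab == "active"))))
})

test_that("bioactivity CSV reading converts units and checks labels", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,target_id,ec50,ec50_units",
               "c1,t1,500,nM", "c2,t1,2,uM", "c3,t1,0.000001,M"), csv)
  rec <- read_bioactivity(csv)
  expect_equal(rec$ec50, c(0.5, 2, 1))
  expect_equal(rec$label, c("active", "inactive", "active"))

  clash <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,target_id,ec50,label",
               "c1,t1,50,active"), clash)
  expect_error(read_bioactivity(clash), "disagrees")
})

test_that("assembled examples have the 30 + 187 feature layout", {
  ex <- tiny_examples()
  feats <- c(grep("^P_", names(ex), value = TRUE),
             grep("^L_", names(ex), value = TRUE))
  expect_length(grep("^P_", feats), 30)
  expect_length(grep("^L_", feats), 187)
  expect_length(feats, 217)
  # protein block first in column order
  expect_true(min(grep("^P_", names(ex))) < min(grep("^L_", names(ex))))
  expect_equal(nrow(ex), nrow(tiny_sim()$records))
})

test_that("assembly excludes and reports unresolvable ids", {
  sim <- tiny_sim()
  records <- sim$records[1:10, ]
  records$target_id[3] <- "NOPE"
  expect_warning(
    ex <- suppressMessages(assemble_examples(records, targets = sim$panel,
                                             compounds = sim$compounds,
                                             panel = sim$panel)),
    "unresolvable")
  expect_equal(nrow(ex), 9)
  expect_equal(attr(ex, "problems")$reason, "unknown target id")
  bad <- dplyr::mutate(records, target_id = "NOPE")
  expect_error(
    suppressWarnings(suppressMessages(
      assemble_examples(bad, targets = sim$panel,
                        compounds = sim$compounds, panel = sim$panel))),
    "no records")
})

test_that("duplicated records produce identical feature vectors", {
  sim <- tiny_sim()
  rec <- sim$records[c(1, 1), ]
  ex <- suppressMessages(assemble_examples(rec, targets = sim$panel,
                                           compounds = sim$compounds,
                                           panel = sim$panel))
  expect_equal(nrow(ex), 2)
  expect_identical(as.numeric(ex[1, -(1:4)]), as.numeric(ex[2, -(1:4)]))
})

test_that("splitting is disjoint, exhaustive, stratified and reproducible", {
  ex <- tiny_examples()
  ex$.row <- seq_len(nrow(ex))
  sp <- split_examples(ex, train_fraction = 0.85, seed = 9)
  expect_length(intersect(sp$train$.row, sp$validation$.row), 0)
  expect_setequal(c(sp$train$.row, sp$validation$.row), ex$.row)
  expect_equal(nrow(sp$train) / nrow(ex), 0.85, tolerance = 0.02)
  # each target keeps both classes on both sides
  for (side in sp) {
    tab <- table(side$target_id, side$label)
    expect_true(all(tab > 0))
  }
  sp2 <- split_examples(ex, train_fraction = 0.85, seed = 9)
  expect_identical(sp$train$.row, sp2$train$.row)
  sp3 <- split_examples(ex, train_fraction = 0.85, seed = 10)
  expect_false(identical(sp$train$.row, sp3$train$.row))
})

test_that("split validation catches tiny strata and bad fractions", {
  ex <- toy_examples(n_active = 1, n_inactive = 30)
  expect_error(split_examples(ex, 0.8), "stratum too small")
  expect_error(split_examples(toy_examples(), train_fraction = 1), "between")
  # the classical grid range yields nine settings
  expect_length(seq(0.50, 0.90, by = 0.05), 9)
})
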