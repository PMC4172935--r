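test_that("majority_vote matches exhaustive enumeration and tie convention", {
  for (n in c(1L, 2L, 3L, 4L, 5L)) {
    for (votes in all_vote_vectors(n)) {
      expect_identical(majority_vote(votes), oracle_vote(votes))
    }
  }
  # even ties resolve to control
  expect_identical(majority_vote(c(1L, -1L)), -1L)
  expect_identical(majority_vote(c(1L, 1L, -1L, -1L)), -1L)
  expect_error(majority_vote(integer(0)), "empty")
  expect_error(majority_vote(c(1L, 0L)), "\\+1 or -1")
})

test_that("metrics follow their arithmetic definitions", {
  m <- compute_metrics(list(tp = 7, fn = 1, tn = 8, fp = 0))
  expect_equal(m$accuracy, 93.75)
  expect_equal(m$specificity, 100)
  expect_equal(m$sensitivity, 87.5)

  deg <- compute_metrics(list(tp = 0, fn = 0, tn = 5, fp = 0))
  expect_equal(deg$specificity, 100)
  expect_true(is.na(deg$sensitivity))

  a <- compute_metrics(list(tp = 3, fn = 2, tn = 4, fp = 1))
  b <- compute_metrics(list(tp = 9, fn = 6, tn = 12, fp = 3))
  expect_equal(a, b) # ratio property: scaling all counts changes nothing

  expect_error(compute_metrics(list(tp = 0, fn = 0, tn = 0, fp = 0)), "zero")
  expect_error(compute_metrics(list(tp = -1, fn = 0, tn = 1, fp = 0)),
               "non-negative")
})

separable_table <- function(n_per_class = 4, seed = 8) {
  generate_feature_table(n_per_class,
                         mean_ad = c(100, 0, 0, 0, 0),
                         mean_control = c(0, 0, 0, 0, 0),
                         sds = rep(10, 5), seed = seed)
}

test_that("all three base learners separate a wide-margin toy set", {
  tab <- separable_table()
  models <- train_base_classifiers(tab, seed = 1, subset = "gm")
  base <- predict_base(models, tab)
  expect_true(all(base[, "svm"] == tab$label))
  expect_true(all(base[, "mlp"] == tab$label))
  expect_true(all(base[, "tree"] == tab$label))
})

test_that("training is deterministic and the ensemble equals the row vote", {
  tab <- separable_table(10)
  probe <- separable_table(10, seed = 99)
  m1 <- train_base_classifiers(tab, seed = 5)
  m2 <- train_base_classifiers(tab, seed = 5)
  expect_identical(predict_base(m1, probe), predict_base(m2, probe))

  base <- predict_base(m1, probe)
  ens <- predict_ensemble(m1, probe)
  expect_identical(ens, as.integer(apply(base, 1, majority_vote)))
})

test_that("flipping training labels flips the tree's predictions", {
  tab <- separable_table(10)
  probe <- separable_table(10, seed = 77)
  flipped <- dplyr::mutate(tab, label = -label)
  t1 <- train_base_classifiers(tab, seed = 2)
  t2 <- train_base_classifiers(flipped, seed = 2)
  expect_identical(predict_base(t2, probe)[, "tree"],
                   -predict_base(t1, probe)[, "tree"])
})

test_that("degenerate training tables are rejected", {
  tab <- separable_table(4)
  expect_error(train_base_classifiers(dplyr::filter(tab, label == 1)),
               "single class")
  expect_error(train_base_classifiers(dplyr::mutate(tab, label = 2L)),
               "\\+1 or -1")
  expect_error(crossvalidate(tab[0, ]), "empty")
  expect_error(crossvalidate(tab, subset = "nope"), "not found")
})

test_that("cross-validation partitions subjects once and is reproducible", {
  tab <- separable_table(12)
  rep1 <- crossvalidate(tab, k = 4, seed = 3)
  rep2 <- crossvalidate(tab, k = 4, seed = 3)
  expect_identical(rep1$metrics, rep2$metrics)
  expect_identical(rep1$predictions, rep2$predictions)
  # every subject appears in exactly one test fold
  expect_identical(sort(rep1$predictions$row), seq_len(nrow(tab)))
  expect_identical(length(rep1$fold), nrow(tab))
  # stratification: each fold holds both classes
  split_truth <- split(rep1$predictions$truth, rep1$predictions$fold)
  expect_true(all(vapply(split_truth,
                         function(v) length(unique(v)) == 2L, logical(1))))
  # pooled ensemble column equals the row-wise majority vote
  expect_identical(rep1$predictions$ensemble,
                   as.integer(apply(as.matrix(
                     rep1$predictions[c("svm", "mlp", "tree")]),
                     1, majority_vote)))
})

test_that("k is reduced with a warning when a class is too small", {
  tab <- separable_table(3)
  expect_warning(rep <- crossvalidate(tab, k = 10, seed = 1), "reducing k")
  expect_identical(rep$k, 3L)
})

test_that("accuracy identity links the three pooled metrics", {
  tab <- generate_feature_table(15, mean_ad = c(3, 0, 0, 1, 0),
                                mean_control = rep(0, 5),
                                sds = rep(1, 5), seed = 13)
  rep <- crossvalidate(tab, k = 5, seed = 13)
  for (i in seq_len(nrow(rep$metrics))) {
    row <- rep$metrics[i, ]
    n_ad <- row$tp + row$fn; n_ctrl <- row$tn + row$fp
    expect_equal(row$accuracy,
                 (row$sensitivity * n_ad + row$specificity * n_ctrl) /
                   (n_ad + n_ctrl))
  }
})

test_that("report tidiers and plot expose the pooled metrics", {
  tab <- separable_table(8)
  rep <- crossvalidate(tab, k = 4, seed = 2, subset = "gm")
  td <- tidy(rep)
  expect_setequal(td$classifier, c("svm", "mlp", "tree", "ensemble"))
  gl <- glance(rep)
  expect_identical(gl$accuracy,
                   td$accuracy[td$classifier == "ensemble"])
  expect_identical(gl$subset, "gm")
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})

test_that("evaluate_subsets stacks one report per feature configuration", {
  tab <- separable_table(6)
  out <- evaluate_subsets(tab, subsets = c("gm", "left+right"), k = 3,
                          seed = 4)
  expect_identical(nrow(out), 8L) # 2 subsets x 4 classifiers
  expect_setequal(unique(out$subset), c("gm", "left+right"))
})
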