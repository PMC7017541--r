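test_that("score_predictions evaluates the printed formulas", {
  cm <- list(tp = 3, fp = 2, tn = 4, fn = 1)
  lv <- confusion_to_labels(cm)
  sc <- score_predictions(lv$pred, lv$truth, positive_class = "P")
  expect_equal(sc$tp, 3)
  expect_equal(sc$fp, 2)
  expect_equal(sc$tn, 4)
  expect_equal(sc$fn, 1)
  expect_equal(sc$sensitivity, 0.75)
  expect_equal(sc$specificity, 2 / 3)
  expect_equal(sc$accuracy, 0.7)
  expect_equal(sc$recall, sc$sensitivity)

  # perfect predictions
  perfect <- score_predictions(lv$truth, lv$truth, positive_class = "P")
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f_measure, 1)
  expect_equal(perfect$kappa, 1)

  expect_error(score_predictions(c("A", "B"), "A"), "length")
  # all-negative data: sensitivity, precision and F are all undefined
  w <- capture_warnings(
    sc0 <- score_predictions(rep("N", 4), rep("N", 4), positive_class = "P")
  )
  expect_true(all(grepl("undefined", w)))
  expect_true(is.nan(sc0$sensitivity))
  expect_equal(sc0$accuracy, 1)
})

test_that("chance-level predictions give kappa near zero", {
  withr::with_seed(404, {
    truth <- sample(c("P", "N"), 10000, replace = TRUE, prob = c(0.6, 0.4))
    pred <- sample(truth)  # matching marginals, independent of truth
  })
  sc <- score_predictions(pred, truth, positive_class = "P")
  expect_lt(abs(sc$kappa), 0.05)
})

test_that("metric identities hold on random confusion matrices", {
  for (s in 1:250) {
    cm <- random_confusion(seed = 5000 + s)
    lv <- confusion_to_labels(cm)
    sc <- suppressWarnings(
      score_predictions(lv$pred, lv$truth, positive_class = "P")
    )
    with(cm, {
      expect_equal(sc$sensitivity, tp / (tp + fn))
      expect_equal(sc$specificity, tn / (tn + fp))
      expect_equal(sc$accuracy, (tp + tn) / (tp + fp + tn + fn))
      # accuracy decomposition: ACC = (SE*P + SP*N)/(P + N)
      P <- tp + fn
      N <- tn + fp
      expect_equal(sc$accuracy,
                   (sc$sensitivity * P + sc$specificity * N) / (P + N))
    })
    # F is the harmonic mean of precision and recall
    if (is.finite(sc$precision) && is.finite(sc$recall) &&
        sc$precision + sc$recall > 0) {
      expect_equal(sc$f_measure,
                   2 * sc$precision * sc$recall / (sc$precision + sc$recall))
    }
    expect_true(all(unlist(sc[c("sensitivity", "specificity", "accuracy")])
                    <= 1, na.rm = TRUE))
    expect_gte(sc$kappa, -1)
    expect_lte(sc$kappa, 1)
  }
})

test_that("multi-class scoring reports accuracy and kappa only", {
  sc <- score_predictions(c("A", "B", "C", "C"), c("A", "B", "C", "A"))
  expect_equal(sc$accuracy, 0.75)
  expect_false(is.na(sc$kappa))
  expect_true(is.na(sc$sensitivity))
})

test_that("ec_sweep recovers separable data and is reproducible", {
  sim <- make_clustered_data(n_points = 60, separation = 8,
                             unlabeled_fraction = 0, seed = 55)
  res <- ec_sweep(sim$data, nmc_values = c(5, 8), iterations = 3,
                  train_fraction = 0.7, r = 50, seed = 55,
                  positive_class = "B", nstart = 4)
  expect_equal(res$nmc, c(5L, 8L))
  expect_true(all(res$accuracy >= 0.95))

  res2 <- ec_sweep(sim$data, nmc_values = c(5, 8), iterations = 3,
                   train_fraction = 0.7, r = 50, seed = 55,
                   positive_class = "B", nstart = 4)
  expect_identical(as.data.frame(res), as.data.frame(res2))

  # per-nmc means lie within the per-iteration range
  detail <- attr(res, "detail")
  for (v in unique(detail$nmc)) {
    accs <- detail$accuracy[detail$nmc == v]
    expect_gte(res$accuracy[res$nmc == v], min(accs))
    expect_lte(res$accuracy[res$nmc == v], max(accs))
  }
})

test_that("degenerate sweep splits are rejected", {
  sim <- make_clustered_data(n_points = 30, unlabeled_fraction = 0, seed = 9)
  expect_error(ec_sweep(sim$data, nmc_values = 5, iterations = 1,
                        train_fraction = 0.999, seed = 1),
               "hidden")
  expect_error(ec_sweep(sim$data, nmc_values = 5, train_fraction = 1.2,
                        seed = 1),
               "train_fraction")
})

test_that("baselines and the EC classifier all solve separable data", {
  sim <- make_clustered_data(n_points = 80, separation = 8,
                             unlabeled_fraction = 0, seed = 66)
  tab <- compare_baselines(sim$data, nmc = 6, r = 50, train_fraction = 0.75,
                           seed = 66, positive_class = "B",
                           k_neighbors = 3, n_trees = 15, nstart = 4)
  expect_setequal(tab$method,
                  c("grp_classifier_ec", "knn", "decision_tree",
                    "random_forest", "ec_random_forest"))
  expect_true(all(c("sensitivity", "specificity", "f_measure",
                    "accuracy", "acc_diff") %in% names(tab)))
  expect_true(all(tab$accuracy >= 0.95))
  expect_true(all(abs(tab$acc_diff) <= 0.05 + 1e-9))
})

test_that("randomized labels drop every method to chance level", {
  sim <- make_clustered_data(n_points = 400, separation = 0,
                             unlabeled_fraction = 0, seed = 88)
  rand <- sim$data
  withr::with_seed(88, {
    rand$class <- sample(c("A", "B"), nrow(rand), replace = TRUE)
  })
  tab <- compare_baselines(rand, nmc = 6, r = 50, train_fraction = 0.5,
                           seed = 88, positive_class = "B",
                           k_neighbors = 5, n_trees = 10, nstart = 2)
  expect_true(all(abs(tab$accuracy - 0.5) <= 0.1))
})

test_that("hand-rolled learners behave on trivially separable input", {
  x <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), ncol = 1)
  y <- c("A", "A", "A", "B", "B", "B")
  test <- matrix(c(0.05, 5.05), ncol = 1)
  expect_equal(knn_classify(x, y, test, k = 3), c("A", "B"))
  tr <- tree_fit(x, y, seed = 1)
  expect_equal(tree_predict(tr, test), c("A", "B"))
  fo <- forest_fit(x, y, n_trees = 11, seed = 1)
  expect_equal(forest_predict(fo, test), c("A", "B"))
})
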