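# A tiny grouping with controlled label structure: three groups over
# 8 points — {1,2,3} mixed 2:1, {4,5} unanimous with an unlabeled member,
# {6,7,8} fully unlabeled.
toy_groups <- function() {
  ec <- tibble::tibble(
    point_id = as.character(1:8),
    k2 = c("c0", "c0", "c0", "c1", "c1", "c0", "c0", "c0"),
    k3 = c("c0", "c0", "c0", "c1", "c1", "c2", "c2", "c2")
  )
  labels <- c("A", "A", "B", "A", NA, NA, NA, NA)
  list(groups = extract_groups(ec, labels = labels), labels = labels)
}

test_that("the three labeling cases are tagged and resolved correctly", {
  toy <- toy_groups()
  gl <- assign_group_labels(toy$groups, toy$labels, r = 101, seed = 6)
  expect_equal(nrow(gl), 3)
  expect_equal(gl$case, c("majority", "unanimous", "nearest-group"))

  # unanimous group: class fixed whatever r and seed
  for (s in c(1, 99)) {
    gl2 <- assign_group_labels(toy$groups, toy$labels, r = 1, seed = s)
    expect_equal(gl2$class[2], "A")
    expect_equal(gl2$case[2], "unanimous")
  }

  # mixed 2:1 group under a fixed seed: majority of 101 draws is A
  expect_equal(gl$class[1], "A")
  expect_equal(sum(gl$votes[[1]]), 101)

  # fully unlabeled group {6,7,8} has representative (c0,c2); candidates
  # are (c0,c0) at similarity 0.5 and (c1,c1) at 0: inherits from group 1
  expect_equal(gl$source_group[3], 1)
  expect_equal(gl$class[3], gl$class[1])
})

test_that("mixed groups converge to the labeled majority as r grows", {
  toy <- toy_groups()
  picks <- vapply(1:50, function(s) {
    assign_group_labels(toy$groups, toy$labels, r = 1001, seed = s)$class[1]
  }, character(1))
  expect_gte(mean(picks == "A"), 0.99)
})

test_that("majority draw frequencies match a direct binomial simulation", {
  # independent oracle: the draw count for class A in a 2:1 group is
  # Binomial(r, 2/3); the observed tally across seeds must match it
  toy <- toy_groups()
  r <- 60
  tallies <- vapply(1:200, function(s) {
    gl <- assign_group_labels(toy$groups, toy$labels, r = r, seed = s)
    v <- gl$votes[[1]]
    if ("A" %in% names(v)) v[["A"]] else 0L
  }, integer(1))
  expect_equal(mean(tallies) / r, 2 / 3, tolerance = 0.02)
})

test_that("singleton labeled groups keep their own label for any r", {
  ec <- tibble::tibble(point_id = as.character(1:3),
                       k2 = c("c0", "c1", "c2"))
  labels <- c("B", "A", "C")
  g <- extract_groups(ec, labels = labels)
  for (r in c(1, 7, 100)) {
    gl <- assign_group_labels(g, labels, r = r, seed = r)
    expect_equal(gl$class, labels)
    expect_equal(unique(gl$case), "unanimous")
  }
})

test_that("nearest_labeled_group maximizes similarity with stated ties", {
  mk <- function(reps, n_labeled) {
    tibble::tibble(
      group_id = seq_along(reps),
      representative = reps,
      size = rep(1L, length(reps)),
      members = as.list(seq_along(reps)),
      member_ids = as.list(as.character(seq_along(reps))),
      n_labeled = n_labeled
    )
  }
  # exact match dominates
  g <- mk(list(c("c0", "c1"), c("c0", "c1"), c("c1", "c1")), c(0L, 1L, 1L))
  expect_equal(nearest_labeled_group(g, 1), 2)

  # 9/10 matching positions beats 6/10
  q <- paste0("c", 1:10)
  a6 <- c(q[1:6], paste0("x", 7:10))
  a9 <- c(q[1:9], "x10")
  g2 <- mk(list(q, a6, a9), c(0L, 1L, 1L))
  expect_equal(nearest_labeled_group(g2, 1), 3)

  # similarity tie: prefer more labeled members, then lowest id
  g3 <- mk(list(c("c0", "c1"), c("c0", "c9"), c("c9", "c1")), c(0L, 1L, 3L))
  expect_equal(nearest_labeled_group(g3, 1), 3)
  g4 <- mk(list(c("c0", "c1"), c("c0", "c9"), c("c9", "c1")), c(0L, 2L, 2L))
  expect_equal(nearest_labeled_group(g4, 1), 2)

  # single labeled candidate
  expect_equal(nearest_labeled_group(g, 3, candidates = 2), 2)
  expect_error(nearest_labeled_group(g, 1, candidates = integer(0)),
               "no labelled group")
})

test_that("fit_predict labels every point and recovers blob structure", {
  sim <- make_clustered_data(n_points = 80, n_features = 2, separation = 8,
                             unlabeled_fraction = 0.5, seed = 17)
  fit <- fit_predict(sim$data, nmc = 8, r = 100, seed = 17)
  pred <- tidy(fit)
  expect_equal(nrow(pred), 80)
  expect_false(anyNA(pred$class_pred))
  # every group member shares its group's class
  per_group <- tapply(pred$class_pred, pred$group_id,
                      function(x) length(unique(x)))
  expect_true(all(per_group == 1))
  # hidden labels recovered on well-separated data
  hidden <- is.na(sim$data$class)
  expect_gte(mean(pred$class_pred[hidden] == sim$truth$true_class[hidden]),
             0.95)
})

test_that("fully labeled pure groups reproduce the input labels", {
  sim <- make_clustered_data(n_points = 40, separation = 10,
                             unlabeled_fraction = 0, seed = 23)
  fit <- fit_predict(sim$data, nmc = 5, r = 50, seed = 23)
  g <- glance(fit)
  if (all(fit$groups$purity == 1, na.rm = TRUE)) {
    expect_equal(g$accuracy_labeled, 1)
    expect_equal(tidy(fit)$class_pred, sim$data$class)
  }
})

test_that("an unlabeled duplicate of a labeled point gets its label", {
  withr::with_seed(31, {
    base <- tibble::tibble(x1 = rnorm(10, sd = 3), x2 = rnorm(10, sd = 3))
  })
  data <- dplyr::bind_rows(base, base[4, ])
  data$class <- c(LETTERS[c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2)], NA)
  fit <- fit_predict(data, nmc = 6, r = 50, seed = 2)
  pred <- tidy(fit)
  # identical feature rows share every k-means cell, hence one group
  expect_equal(pred$group_id[11], pred$group_id[4])
  expect_equal(pred$class_pred[11], pred$class_pred[4])
  # and when that group holds only the pair, the label is the donor's
  if (sum(pred$group_id == pred$group_id[4]) == 2) {
    expect_equal(pred$class_pred[11], "B")
  }
})

test_that("fit_predict validates its inputs", {
  sim <- make_clustered_data(n_points = 20, seed = 3)
  nolab <- sim$data
  nolab$class <- NA_character_
  expect_error(fit_predict(nolab, nmc = 4, seed = 1), "labelled")
  expect_error(fit_predict(sim$data, nmc = 1, seed = 1), "nmc")
  expect_error(fit_predict(dplyr::select(sim$data, -"class"),
                           nmc = 4, seed = 1), "label")
})
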