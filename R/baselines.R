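# Small self-contained baseline learners (k-nearest neighbours, a Gini
# decision tree, and a bagged forest). No KNN/tree/forest package ships
# with this toolchain, so minimal versions live here; they exist only as
# comparison points for the EC classifier, not as general-purpose learners.

#' Baseline learners: KNN, decision tree, bagged forest
#'
#' Minimal reference implementations used by [compare_baselines()].
#' `knn_classify()` votes among the `k` Euclidean-nearest training points
#' (distance-ties included, label-ties broken lexicographically).
#' `tree_fit()` grows a binary CART-style tree on midpoint thresholds
#' chosen by Gini impurity; `forest_fit()` bags `n_trees` such trees on
#' bootstrap samples with a random sqrt(p) feature subset per tree and
#' predicts by majority vote.
#'
#' @param train_x,x Numeric feature matrices (rows = points).
#' @param train_y,y Character class labels for the training rows.
#' @param test_x Numeric matrix of points to classify.
#' @param k Number of neighbours.
#' @return `knn_classify()`, `tree_predict()` and `forest_predict()`
#'   return a character vector of predicted classes.
#' @export
knn_classify <- function(train_x, train_y, test_x, k = 5) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  k <- min(k, nrow(train_x))
  apply(test_x, 1, function(p) {
    d <- sqrt(colSums((t(train_x) - p)^2))
    nn <- order(d)[seq_len(k)]
    majority_label(train_y[nn])
  })
}

#' @rdname knn_classify
#' @param max_depth,min_split Tree growth limits: maximum depth and the
#'   smallest node that may still be split.
#' @param mtry Features considered (per tree); default all for a single
#'   tree, `sqrt(p)` within [forest_fit()].
#' @param seed Integer seed.
#' @export
tree_fit <- function(train_x, train_y, max_depth = 10, min_split = 5,
                     mtry = NULL, seed = 1) {
  train_x <- as.matrix(train_x)
  p <- ncol(train_x)
  mtry <- mtry %||% p
  withr::with_seed(seed, {
    feats <- sort(sample.int(p, min(mtry, p)))
    node <- grow_tree(train_x, train_y, feats, depth = 0,
                      max_depth = max_depth, min_split = min_split)
  })
  structure(list(root = node), class = "ecspace_tree")
}

gini_impurity <- function(y) {
  p <- table(y) / length(y)
  1 - sum(p^2)
}

grow_tree <- function(x, y, feats, depth, max_depth, min_split) {
  if (depth >= max_depth || length(y) < min_split ||
      length(unique(y)) == 1) {
    return(list(leaf = TRUE, class = majority_label(y)))
  }
  best <- NULL
  base <- gini_impurity(y)
  for (j in feats) {
    v <- x[, j]
    cuts <- sort(unique(v))
    if (length(cuts) < 2) next
    thr <- (head(cuts, -1) + cuts[-1]) / 2
    if (length(thr) > 32) thr <- stats::quantile(v, probs = (1:32) / 33)
    for (t in thr) {
      left <- v <= t
      nl <- sum(left)
      if (nl == 0 || nl == length(y)) next
      g <- (nl * gini_impurity(y[left]) +
              (length(y) - nl) * gini_impurity(y[!left])) / length(y)
      if (is.null(best) || g < best$g) best <- list(j = j, t = t, g = g)
    }
  }
  if (is.null(best) || best$g >= base) {
    return(list(leaf = TRUE, class = majority_label(y)))
  }
  left <- x[, best$j] <= best$t
  list(
    leaf = FALSE, feature = best$j, threshold = best$t,
    left = grow_tree(x[left, , drop = FALSE], y[left], feats,
                     depth + 1, max_depth, min_split),
    right = grow_tree(x[!left, , drop = FALSE], y[!left], feats,
                      depth + 1, max_depth, min_split)
  )
}

#' @rdname knn_classify
#' @param fit A fitted tree or forest.
#' @export
tree_predict <- function(fit, test_x) {
  test_x <- as.matrix(test_x)
  apply(test_x, 1, function(p) {
    node <- fit$root
    while (!node$leaf) {
      node <- if (p[node$feature] <= node$threshold) node$left else node$right
    }
    node$class
  })
}

#' @rdname knn_classify
#' @param n_trees Number of bagged trees.
#' @export
forest_fit <- function(train_x, train_y, n_trees = 50, max_depth = 10,
                       min_split = 5, seed = 1) {
  train_x <- as.matrix(train_x)
  n <- nrow(train_x)
  mtry <- max(1L, floor(sqrt(ncol(train_x))))
  trees <- lapply(seq_len(n_trees), function(b) {
    bs <- derive_seed(seed, b)
    idx <- withr::with_seed(bs, sample.int(n, n, replace = TRUE))
    tree_fit(train_x[idx, , drop = FALSE], train_y[idx],
             max_depth = max_depth, min_split = min_split,
             mtry = mtry, seed = derive_seed(bs, 1L))
  })
  structure(list(trees = trees), class = "ecspace_forest")
}

#' @rdname knn_classify
#' @export
forest_predict <- function(fit, test_x) {
  votes <- vapply(fit$trees, tree_predict, character(nrow(as.matrix(test_x))),
                  test_x = test_x)
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  apply(votes, 1, majority_label)
}
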