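#' Score predictions against known labels
#'
#' Builds the confusion matrix and the usual derived measures. For a
#' binary task with a named positive class the full panel is reported:
#' sensitivity `TP/(TP+FN)` (= recall), specificity `TN/(TN+FP)`,
#' accuracy `(TP+TN)/(TP+FN+TN+FP)`, precision `TP/(TP+FP)`, the
#' F-measure (harmonic mean of precision and recall) and Cohen's kappa
#' `(po - pe)/(1 - pe)` with expected agreement from the marginal
#' products. With more than two classes only accuracy and kappa are
#' defined here; the other columns are `NA`. Ratios with a zero
#' denominator are returned as `NaN` with a warning.
#'
#' @param pred Predicted classes: a character vector, or the tibble from
#'   [tidy()] on a fitted classifier (its `class_pred` column is used,
#'   and `truth` defaults to its `class_observed`).
#' @param truth True classes, aligned with `pred`.
#' @param positive_class The class counted as positive (binary tasks).
#'   Defaults to the lexicographically largest class, with a message.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`, `precision`, `recall`, `f_measure`,
#'   `kappa`, `n`.
#' @examples
#' score_predictions(c("A", "A", "B"), c("A", "B", "B"),
#'                   positive_class = "A")
#' @export
score_predictions <- function(pred, truth = NULL, positive_class = NULL) {
  if (is.data.frame(pred)) {
    truth <- truth %||% pred$class_observed
    pred <- pred$class_pred
  }
  if (is.null(truth)) abort("`truth` is required.")
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    abort("`pred` and `truth` must have the same length.")
  }
  keep <- !is.na(truth) & !is.na(pred)
  pred <- pred[keep]
  truth <- truth[keep]
  n <- length(truth)
  if (n == 0) abort("no scored points: all entries missing.")
  classes <- sort(unique(c(truth, pred)))
  acc <- mean(pred == truth)
  kap <- cohens_kappa(truth, pred, classes)
  if (length(classes) > 2) {
    return(tibble(
      tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
      fn = NA_integer_, sensitivity = NA_real_, specificity = NA_real_,
      accuracy = acc, precision = NA_real_, recall = NA_real_,
      f_measure = NA_real_, kappa = kap, n = n
    ))
  }
  if (is.null(positive_class)) {
    positive_class <- classes[length(classes)]
    message("using `positive_class` = \"", positive_class, "\"")
  }
  tp <- sum(truth == positive_class & pred == positive_class)
  fn <- sum(truth == positive_class & pred != positive_class)
  fp <- sum(truth != positive_class & pred == positive_class)
  tn <- sum(truth != positive_class & pred != positive_class)
  se <- safe_ratio(tp, tp + fn, "sensitivity")
  sp <- safe_ratio(tn, tn + fp, "specificity")
  prec <- safe_ratio(tp, tp + fp, "precision")
  f <- safe_ratio(2 * prec * se, prec + se, "F-measure")
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = se, specificity = sp, accuracy = acc,
    precision = prec, recall = se, f_measure = f, kappa = kap, n = n
  )
}

safe_ratio <- function(num, den, what) {
  if (is.na(den) || den == 0) {
    warn(sprintf("%s undefined: zero denominator.", what))
    return(NaN)
  }
  num / den
}

cohens_kappa <- function(truth, pred, classes) {
  n <- length(truth)
  po <- mean(truth == pred)
  pe <- sum(vapply(classes, function(cl) {
    mean(truth == cl) * mean(pred == cl)
  }, double(1)))
  if (pe == 1) return(NaN)
  (po - pe) / (1 - pe)
}

#' Sweep nmc and measure hidden-label accuracy
#'
#' For each value of `nmc` and each iteration, hides the labels of a
#' random stratified share `1 - train_fraction` of the labelled points,
#' runs [fit_predict()] on the partially labelled data, and scores the
#' predictions on the hidden points only. "Stratified" means every class
#' contributes the same fraction of its labelled points to the hidden
#' set, so class balance is preserved at each iteration.
#'
#' @inheritParams fit_predict
#' @param nmc_values Integer vector of nmc levels to test.
#' @param iterations Random splits per nmc level.
#' @param train_fraction Fraction of labelled points whose labels are
#'   kept; must be in (0, 1) and leave at least one hidden point.
#' @param positive_class Positive class for binary metrics.
#' @param .detail If `TRUE`, return the per-iteration table instead of
#'   per-nmc means.
#' @return A tibble of per-nmc means of sensitivity, specificity,
#'   accuracy, F-measure and kappa, plus the mean reduction ratio and
#'   group count; class `"ec_sweep"`.
#' @export
ec_sweep <- function(data, nmc_values = c(10L, 20L, 30L, 40L, 50L),
                     iterations = 100, train_fraction = 0.8, r = 100,
                     seed = 1, positive_class = NULL, label_col = "class",
                     id_col = "point_id", nstart = 10, .detail = FALSE) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be strictly between 0 and 1.")
  }
  parts <- as_feature_parts(data, label_col = label_col, id_col = id_col)
  if (is.null(parts$labels) || all(is.na(parts$labels))) {
    abort("labelled data are required for a sweep.")
  }
  labels <- parts$labels
  labeled_idx <- which(!is.na(labels))
  grid <- tidyr::expand_grid(nmc = as.integer(nmc_values),
                             iteration = seq_len(iterations))
  rows <- purrr::pmap(grid, function(nmc, iteration) {
    split_seed <- derive_seed(seed, nmc * 1000L + iteration)
    hidden <- withr::with_seed(split_seed, {
      unlist(lapply(split(labeled_idx, labels[labeled_idx]), function(idx) {
        n_hide <- round(length(idx) * (1 - train_fraction))
        sample(idx, n_hide)
      }), use.names = FALSE)
    })
    if (length(hidden) == 0) {
      abort("`train_fraction` leaves no hidden point to evaluate on.")
    }
    masked <- data
    masked[[label_col]][hidden] <- NA
    fit <- fit_predict(masked, nmc = nmc, r = r, seed = split_seed,
                       nstart = nstart, label_col = label_col,
                       id_col = id_col)
    sc <- suppressMessages(score_predictions(
      fit$predictions$class_pred[hidden], labels[hidden],
      positive_class = positive_class
    ))
    bind_cols(
      tibble(nmc = nmc, iteration = iteration,
             n_hidden = length(hidden),
             n_groups = nrow(fit$groups),
             reduction_ratio = reduction_ratio(fit$groups)),
      sc[c("sensitivity", "specificity", "accuracy", "f_measure", "kappa")]
    )
  })
  detail <- bind_rows(rows)
  if (.detail) return(detail)
  out <- detail |>
    group_by(.data$nmc) |>
    summarise(across(
      c("n_groups", "reduction_ratio", "sensitivity", "specificity",
        "accuracy", "f_measure", "kappa"),
      ~ mean(.x, na.rm = TRUE)
    ), .groups = "drop")
  structure(out, detail = detail, class = c("ec_sweep", class(out)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.ec_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[c("nmc", "sensitivity", "specificity", "accuracy")],
    -"nmc", names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$nmc, .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "nmc (largest number of clusters)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Compare the EC classifier with baseline learners
#'
#' Runs one stratified train/test experiment: the EC classifier sees the
#' data with the test labels hidden (transductive), while the baselines
#' are trained on the labelled part of the original numeric features and
#' scored on the held-out points. Baselines are k-nearest neighbours, a
#' Gini-split decision tree, a bagged random forest on the original
#' features, and the same forest on the one-hot-encoded EC matrix
#' (`ec_random_forest`). The `acc_diff` column is the EC classifier's
#' accuracy minus each method's accuracy.
#'
#' @inheritParams fit_predict
#' @param train_fraction Fraction of labelled points used for training.
#' @param positive_class Positive class for binary metrics.
#' @param k_neighbors Neighbourhood size for KNN.
#' @param n_trees Trees in the random forests.
#' @return A tibble with one row per method: `method`, `sensitivity`,
#'   `specificity`, `f_measure`, `accuracy`, `acc_diff`.
#' @export
compare_baselines <- function(data, nmc = 30, r = 100, train_fraction = 0.8,
                              seed = 1, positive_class = NULL,
                              k_neighbors = 5, n_trees = 50,
                              label_col = "class", id_col = "point_id",
                              nstart = 10) {
  parts <- as_feature_parts(data, label_col = label_col, id_col = id_col)
  if (is.null(parts$labels) || all(is.na(parts$labels))) {
    abort("labelled data are required for a comparison.")
  }
  labels <- parts$labels
  labeled_idx <- which(!is.na(labels))
  hidden <- withr::with_seed(derive_seed(seed, 77L), {
    unlist(lapply(split(labeled_idx, labels[labeled_idx]), function(idx) {
      sample(idx, round(length(idx) * (1 - train_fraction)))
    }), use.names = FALSE)
  })
  if (length(hidden) == 0) abort("no held-out point to evaluate on.")
  train <- setdiff(labeled_idx, hidden)

  masked <- data
  masked[[label_col]][hidden] <- NA
  fit <- fit_predict(masked, nmc = nmc, r = r, seed = seed,
                     nstart = nstart, label_col = label_col,
                     id_col = id_col)
  x <- parts$values
  ec_x <- onehot_ec(fit$ec)
  preds <- list(
    grp_classifier_ec = fit$predictions$class_pred[hidden],
    knn = knn_classify(x[train, , drop = FALSE], labels[train],
                       x[hidden, , drop = FALSE], k = k_neighbors),
    decision_tree = {
      tr <- tree_fit(x[train, , drop = FALSE], labels[train],
                     seed = derive_seed(seed, 101L))
      tree_predict(tr, x[hidden, , drop = FALSE])
    },
    random_forest = {
      fo <- forest_fit(x[train, , drop = FALSE], labels[train],
                       n_trees = n_trees, seed = derive_seed(seed, 102L))
      forest_predict(fo, x[hidden, , drop = FALSE])
    },
    ec_random_forest = {
      fo <- forest_fit(ec_x[train, , drop = FALSE], labels[train],
                       n_trees = n_trees, seed = derive_seed(seed, 103L))
      forest_predict(fo, ec_x[hidden, , drop = FALSE])
    }
  )
  scores <- purrr::imap(preds, function(p, nm) {
    sc <- suppressMessages(score_predictions(p, labels[hidden],
                                             positive_class = positive_class))
    bind_cols(tibble(method = nm),
              sc[c("sensitivity", "specificity", "f_measure", "accuracy")])
  })
  out <- bind_rows(scores)
  out$acc_diff <- out$accuracy[1] - out$accuracy
  out
}

# One-hot encoding of the categorical EC matrix for learners that need
# numeric inputs.
onehot_ec <- function(ec) {
  kcols <- grep("^k[0-9]+$", names(ec), value = TRUE)
  blocks <- lapply(kcols, function(cn) {
    f <- factor(ec[[cn]])
    m <- outer(f, levels(f), `==`) * 1
    colnames(m) <- paste0(cn, "_", levels(f))
    m
  })
  do.call(cbind, blocks)
}
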