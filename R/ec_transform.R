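#' Run k-means once and return canonical categorical assignments
#'
#' Clusters the feature rows of `data` into `k` clusters with k-means and
#' returns one categorical token per point. Tokens are renumbered by order
#' of first appearance (`"c0"`, `"c1"`, ...) so the output does not depend
#' on k-means' internal cluster numbering. When `k` exceeds the number of
#' distinct feature rows, the effective number of clusters is capped at
#' that count (with a warning): k-means is undefined beyond it.
#'
#' @param data A data frame of points: numeric feature columns plus an
#'   optional label column and an optional identifier column (both ignored
#'   here beyond being excluded from the feature matrix).
#' @param k Number of clusters (positive integer).
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @param nstart Number of random restarts; the solution with the smallest
#'   total within-cluster sum of squares is kept.
#' @param iter_max Maximum k-means iterations per restart.
#' @param init Center initialization: `"plusplus"` (default) spreads the
#'   initial centers out by sampling each new center with probability
#'   proportional to its squared distance from the nearest chosen center;
#'   `"random"` samples centers uniformly among distinct rows.
#' @param standardize If `TRUE`, features are z-scored before clustering.
#' @param label_col,id_col Names of the label and identifier columns.
#' @return A character vector of length `nrow(data)` with tokens
#'   `"c0"`, `"c1"`, ... (at most `min(k, distinct rows)` distinct values).
#' @examples
#' pts <- tibble::tibble(x = c(0, 0.1, 10, 10.1), y = c(0, 0, 5, 5))
#' cluster_once(pts, k = 2, seed = 1)
#' @export
cluster_once <- function(data, k, seed, nstart = 10, iter_max = 300,
                         init = c("plusplus", "random"), standardize = FALSE,
                         label_col = "class", id_col = "point_id") {
  init <- match.arg(init)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    abort("`k` must be a single integer >= 1.")
  }
  k <- as.integer(k)
  parts <- as_feature_parts(data, label_col = label_col, id_col = id_col)
  x <- parts$values
  if (standardize) x <- scale_features(x)
  cluster_matrix_once(x, k, seed, nstart, iter_max, init)
}

# Core clustering on a bare numeric matrix (shared by cluster_once and
# ec_transform so the matrix is validated and scaled only once).
cluster_matrix_once <- function(x, k, seed, nstart, iter_max, init) {
  ux <- unique(x)
  k_eff <- min(k, nrow(ux))
  if (k_eff < k) {
    warn(sprintf(
      "k = %d exceeds the %d distinct point(s); using k = %d.",
      k, nrow(ux), k_eff
    ))
  }
  if (k_eff == 1) return(rep("c0", nrow(x)))
  assign <- withr::with_seed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      centers <- if (init == "plusplus") {
        kmeanspp_centers(ux, k_eff)
      } else {
        ux[sample.int(nrow(ux), k_eff), , drop = FALSE]
      }
      fit <- suppressWarnings(
        kmeans(x, centers = centers, iter.max = iter_max, algorithm = "Lloyd")
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best$cluster
  })
  canonicalize_tokens(assign)
}

# k-means++ style seeding: first center uniform among distinct rows, each
# further center sampled with probability proportional to squared distance
# from the nearest center already chosen.
kmeanspp_centers <- function(ux, k) {
  n <- nrow(ux)
  chosen <- integer(k)
  chosen[1] <- sample.int(n, 1)
  d2 <- rowSums((ux - matrix(ux[chosen[1], ], n, ncol(ux), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    chosen[j + 1] <- sample.int(n, 1, prob = p)
    nd2 <- rowSums((ux - matrix(ux[chosen[j + 1], ], n, ncol(ux),
                                byrow = TRUE))^2)
    d2 <- pmin(d2, nd2)
  }
  ux[chosen, , drop = FALSE]
}

# Renumber arbitrary cluster ids as c0, c1, ... by order of first appearance.
canonicalize_tokens <- function(assign) {
  first <- unique(assign)
  paste0("c", match(assign, first) - 1L)
}

scale_features <- function(x) {
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  scale(x, center = TRUE, scale = sds)
}

#' Transform a feature table into the ensemble clustering (EC) space
#'
#' Runs k-means once for every k in `2:nmc` and records, for each point,
#' the cluster token it received at each k. The result is the categorical
#' matrix `cMat`: one row per point and `nmc - 1` columns named
#' `k2 ... k<nmc>`. Each column uses its own seed derived deterministically
#' from `(seed, k)`, so the first `nmc1 - 1` columns at a larger `nmc2`
#' are identical to the full transform at `nmc1` (prefix property), and the
#' whole transform is reproducible from the master seed.
#'
#' Unlabelled points take part in the clustering exactly like labelled
#' ones; the transform is transductive by construction.
#'
#' @inheritParams cluster_once
#' @param nmc Largest number of clusters (>= 2); the EC dimension is
#'   `nmc - 1`.
#' @return A tibble of class `"ec_mat"`: a `point_id` column followed by
#'   categorical columns `k2 ... k<nmc>`. Attributes `k_values` and
#'   `seeds` record the k grid and the per-column seeds; attribute
#'   `labels` carries the label vector (NA = unlabelled) when `data` has
#'   a label column.
#' @examples
#' pts <- tibble::tibble(x = rnorm(20), y = rnorm(20))
#' ec <- ec_transform(pts, nmc = 11, seed = 7)
#' dim(ec)  # 20 points, 1 id column + 10 categorical columns
#' @export
ec_transform <- function(data, nmc, seed, nstart = 10, iter_max = 300,
                         init = c("plusplus", "random"), standardize = FALSE,
                         label_col = "class", id_col = "point_id") {
  init <- match.arg(init)
  if (!is.numeric(nmc) || length(nmc) != 1 || is.na(nmc) || nmc < 2) {
    abort("`nmc` must be a single integer >= 2.")
  }
  nmc <- as.integer(nmc)
  parts <- as_feature_parts(data, label_col = label_col, id_col = id_col)
  x <- parts$values
  if (standardize) x <- scale_features(x)
  k_values <- 2:nmc
  seeds <- vapply(k_values, function(k) derive_seed(seed, k), integer(1))
  cols <- lapply(seq_along(k_values), function(j) {
    cluster_matrix_once(x, k_values[j], seeds[j], nstart, iter_max, init)
  })
  names(cols) <- paste0("k", k_values)
  out <- bind_cols(tibble(point_id = parts$ids), as_tibble(cols))
  new_ec_mat(out, k_values = k_values, seeds = seeds, labels = parts$labels)
}

new_ec_mat <- function(x, k_values, seeds = NULL, labels = NULL) {
  structure(
    x,
    k_values = k_values,
    seeds = seeds,
    labels = labels,
    class = c("ec_mat", class(x))
  )
}

#' Read or write an EC matrix as CSV
#'
#' The on-disk form mirrors the in-memory tibble: a `point_id` column and
#' token columns `k2 ... k<nmc>`.
#'
#' @param path File path.
#' @return `read_ec_csv()` returns an `"ec_mat"` tibble.
#' @export
read_ec_csv <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  kcols <- grep("^k[0-9]+$", names(x), value = TRUE)
  if (!"point_id" %in% names(x) || length(kcols) == 0) {
    abort("EC CSV must have a `point_id` column and `k<j>` token columns.")
  }
  k_values <- sort(as.integer(sub("^k", "", kcols)))
  x <- x[c("point_id", paste0("k", k_values))]
  new_ec_mat(x, k_values = k_values)
}

#' @rdname read_ec_csv
#' @param ec An `"ec_mat"` tibble.
#' @export
write_ec_csv <- function(ec, path) {
  readr::write_csv(as_tibble(ec), path)
  invisible(path)
}
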