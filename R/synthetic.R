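#' Generate labelled/unlabelled point clouds with known structure
#'
#' Draws isotropic Gaussian clouds (unit spread) at separated centres,
#' assigns each cluster a class, then optionally replaces a fraction of
#' the points with exact copies of earlier points (duplicate structure:
#' EC-identical rows must collapse into groups) and masks a fraction of
#' the labels uniformly at random. `separation` is the distance between
#' consecutive cluster centres in multiples of the within-cloud spread;
#' values >= 5 give essentially non-overlapping classes.
#'
#' @param n_points Total number of points.
#' @param n_features Feature-space dimension.
#' @param n_clusters Number of Gaussian clouds.
#' @param classes Class label per cluster (recycled); default alternates
#'   `"A"`/`"B"` over the clusters.
#' @param separation Centre-to-centre distance in spread units.
#' @param unlabeled_fraction Fraction of points whose label is masked.
#' @param duplicate_fraction Fraction of points that are exact copies of
#'   other points.
#' @param seed Integer seed; the output is fully reproducible.
#' @return A list with `data` (tibble: `point_id`, `class` with NA for
#'   masked points, features `x1..`) and `truth` (tibble: `point_id`,
#'   `true_class`, `cluster`).
#' @examples
#' sim <- make_clustered_data(n_points = 50, separation = 8, seed = 1)
#' dplyr::count(sim$truth, true_class)
#' @export
make_clustered_data <- function(n_points = 200, n_features = 2,
                                n_clusters = 2, classes = NULL,
                                separation = 6, unlabeled_fraction = 0.2,
                                duplicate_fraction = 0, seed = 1) {
  stopifnot(n_points >= 1, n_features >= 1, n_clusters >= 1)
  if (unlabeled_fraction < 0 || unlabeled_fraction > 1 ||
      duplicate_fraction < 0 || duplicate_fraction > 1) {
    abort("fractions must lie in [0, 1].")
  }
  classes <- classes %||% c("A", "B")
  classes <- rep_len(as.character(classes), n_clusters)
  n_dup <- floor(n_points * duplicate_fraction)
  n_base <- n_points - n_dup
  if (n_base < 1) abort("`duplicate_fraction` leaves no base point.")
  withr::with_seed(seed, {
    # centres on a line, `separation` spread-units apart
    centers <- matrix(0, n_clusters, n_features)
    centers[, 1] <- (seq_len(n_clusters) - 1) * separation
    cluster <- sort(rep_len(seq_len(n_clusters), n_base))
    x <- centers[cluster, , drop = FALSE] +
      matrix(rnorm(n_base * n_features), n_base, n_features)
    if (n_dup > 0) {
      src <- sample.int(n_base, n_dup, replace = TRUE)
      x <- rbind(x, x[src, , drop = FALSE])
      cluster <- c(cluster, cluster[src])
    }
    true_class <- classes[cluster]
    masked <- true_class
    n_mask <- round(n_points * unlabeled_fraction)
    if (n_mask > 0) masked[sample.int(n_points, n_mask)] <- NA_character_
  })
  colnames(x) <- paste0("x", seq_len(n_features))
  ids <- as.character(seq_len(n_points))
  list(
    data = bind_cols(tibble(point_id = ids, class = masked), as_tibble(x)),
    truth = tibble(point_id = ids, true_class = true_class,
                   cluster = as.integer(cluster))
  )
}

#' Worked 20-point EC matrix
#'
#' The printed 20 x 10 categorical matrix used throughout the
#' documentation: 20 points transformed with nmc = 11 (columns k2..k11).
#' It is a fixed fixture, not a regeneration target — the k-means runs
#' behind it are not reproducible bit-exactly.
#'
#' @return An `"ec_mat"` tibble with 20 rows and columns `point_id`,
#'   `k2` ... `k11`.
#' @examples
#' extract_groups(table1_fixture())
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_ec_space.csv", package = "ecspace",
                      mustWork = TRUE)
  read_ec_csv(path)
}

#' Published group-size distribution fixture
#'
#' The printed 14-row size distribution of a 894-point dataset that
#' collapsed to 449 groups at nmc = 30 (a 50% reduction): one row per
#' occurring group size with the number of groups at that size and the
#' points they account for.
#'
#' @return A tibble with columns `size`, `n_groups`, `n_points`,
#'   `ratio_unique`, `ratio_all`.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_size_distribution.csv",
                      package = "ecspace", mustWork = TRUE)
  out <- readr::read_csv(path, col_types = "iii")
  out$ratio_unique <- out$n_groups / sum(out$n_groups)
  out$ratio_all <- out$n_points / sum(out$n_points)
  out
}
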