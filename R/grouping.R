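#' Collapse identical EC-space rows into groups
#'
#' Two points belong to the same group when their categorical rows agree in
#' every column, i.e. they fell in the same cluster at every k. Groups are
#' numbered by the first-occurring member; members are listed in ascending
#' row order. The groups partition the points, so group sizes always sum
#' to the number of points.
#'
#' @param ec An `"ec_mat"` tibble from [ec_transform()] or [read_ec_csv()].
#' @param labels Optional label vector aligned with the rows of `ec`
#'   (NA = unlabelled). Defaults to the labels recorded on `ec`, if any.
#'   When available, per-group label counts and [group purity][group_purity]
#'   are included.
#' @return A tibble of class `"ec_groups"` with one row per group:
#'   `group_id`, `representative` (list-column of token vectors), `size`,
#'   `members` (list-column of row indices), `member_ids` (list-column of
#'   point identifiers) and, when labels are known, `n_labeled` and
#'   `purity`.
#' @examples
#' ec <- table1_fixture()
#' groups <- extract_groups(ec)
#' nrow(groups)  # 11 groups among the 20 points
#' @export
extract_groups <- function(ec, labels = NULL) {
  stopifnot(is.data.frame(ec), nrow(ec) > 0)
  labels <- labels %||% attr(ec, "labels")
  kcols <- grep("^k[0-9]+$", names(ec), value = TRUE)
  if (length(kcols) == 0) abort("`ec` has no categorical `k<j>` columns.")
  key <- do.call(paste, c(ec[kcols], sep = "\r"))
  gid <- match(key, unique(key))
  members <- split(seq_along(gid), gid)
  reps <- lapply(members, function(m) {
    unname(vapply(ec[kcols], function(col) col[m[1]], character(1)))
  })
  out <- tibble(
    group_id = seq_along(members),
    representative = unname(reps),
    size = unname(lengths(members)),
    members = unname(members),
    member_ids = lapply(unname(members), function(m) ec$point_id[m])
  )
  if (!is.null(labels)) {
    if (length(labels) != nrow(ec)) {
      abort("`labels` must have one entry per row of `ec`.")
    }
    labels <- as.character(labels)
    out$n_labeled <- vapply(
      out$members, function(m) sum(!is.na(labels[m])), integer(1)
    )
    out$purity <- vapply(
      out$members, function(m) label_purity(labels[m]), double(1)
    )
  }
  structure(out, n_points = nrow(ec), labels = labels,
            class = c("ec_groups", class(out)))
}

#' Similarity of two points in the EC space
#'
#' The fraction of categorical coordinates at which the two vectors agree:
#' the mean of the boolean identity function over the EC dimensions. Note
#' the denominator is the EC dimension (`nmc - 1`), not the number of
#' points. Two points are in the same group iff their similarity is 1.
#'
#' @param a,b Character vectors of cluster tokens, equal length.
#' @return A fraction in `[0, 1]`.
#' @examples
#' ec_similarity(c("c0", "c1", "c2"), c("c0", "c1", "c0"))  # 2/3
#' @export
ec_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have the same length.")
  }
  if (length(a) == 0) abort("vectors must be non-empty.")
  mean(a == b)
}

#' Purity of a group's labelled members
#'
#' The sum over classes of the squared class probabilities among the
#' labelled members of a group: 1 for a pure group, `1/#classes` at the
#' uniform floor. Probabilities are computed over labelled members only;
#' a group with no labelled member has undefined purity, returned as `NA`.
#'
#' @param labels Character vector of the group's member labels
#'   (NA = unlabelled).
#' @return A value in `(0, 1]`, or `NA_real_` when no member is labelled.
#' @examples
#' label_purity(c("A", "A", "B"))  # (2/3)^2 + (1/3)^2 = 5/9
#' @export
label_purity <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) return(NA_real_)
  p <- table(labels) / length(labels)
  sum(p^2)
}

#' Group purity for every group in a grouping
#'
#' @param groups An `"ec_groups"` tibble.
#' @param labels Label vector aligned with the original points
#'   (NA = unlabelled).
#' @return `groups` with (re)computed `n_labeled` and `purity` columns.
#' @export
group_purity <- function(groups, labels) {
  labels <- as.character(labels)
  groups$n_labeled <- vapply(
    groups$members, function(m) sum(!is.na(labels[m])), integer(1)
  )
  groups$purity <- vapply(
    groups$members, function(m) label_purity(labels[m]), double(1)
  )
  attr(groups, "labels") <- labels
  groups
}

#' Distribution of group sizes
#'
#' Tabulates how many groups ("unique points") occur at each size and how
#' many original points they account for. `ratio_unique` is the share of
#' groups at that size; `ratio_all` the share of original points.
#'
#' @param groups An `"ec_groups"` tibble.
#' @return A tibble with columns `size`, `n_groups`, `n_points`,
#'   `ratio_unique`, `ratio_all`, ordered by increasing size.
#' @examples
#' size_distribution(extract_groups(table1_fixture()))
#' @export
size_distribution <- function(groups) {
  tab <- table(groups$size)
  out <- tibble(
    size = as.integer(names(tab)),
    n_groups = as.integer(tab)
  )
  out$n_points <- out$size * out$n_groups
  out$ratio_unique <- out$n_groups / sum(out$n_groups)
  out$ratio_all <- out$n_points / sum(out$n_points)
  arrange(out, .data$size)
}

#' Data reduction achieved by duplicate collapsing
#'
#' The number of groups divided by the number of points: the relative size
#' of the data after every set of EC-identical points is replaced by its
#' single representative. 1 means no reduction (all points distinct in EC
#' space).
#'
#' @param groups An `"ec_groups"` tibble.
#' @return A fraction in `(0, 1]`.
#' @export
reduction_ratio <- function(groups) {
  nrow(groups) / sum(groups$size)
}

#' Write a grouping to CSV
#'
#' One row per group; list-columns are collapsed with `|`.
#'
#' @param groups An `"ec_groups"` tibble.
#' @param path Output file path.
#' @export
write_groups_csv <- function(groups, path) {
  flat <- tibble(
    group_id = groups$group_id,
    representative = vapply(groups$representative, paste,
                            character(1), collapse = "|"),
    size = groups$size,
    member_ids = vapply(groups$member_ids, paste,
                        character(1), collapse = "|")
  )
  if ("purity" %in% names(groups)) {
    flat$n_labeled <- groups$n_labeled
    flat$purity <- groups$purity
  }
  readr::write_csv(flat, path)
  invisible(path)
}

#' Plot the group-size distribution
#'
#' Bar chart of the number of groups at each size, optionally comparing
#' several groupings (e.g. different `nmc` values).
#'
#' @param ... Named `"ec_groups"` tibbles; names become the legend entries.
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(...) {
  gs <- list(...)
  if (is.null(names(gs)) || any(names(gs) == "")) {
    names(gs) <- paste0("grouping ", seq_along(gs))
  }
  df <- bind_rows(lapply(gs, size_distribution), .id = "grouping")
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$size), y = .data$n_groups, fill = .data$grouping
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "group size", y = "number of groups (unique points)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
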