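#' Label EC groups by the three-case rule
#'
#' Every group is classified as a unit. Three cases arise from the labels
#' of its members:
#'
#' * **unanimous** — all labelled members share one class; the group takes
#'   that class regardless of `r` and `seed`.
#' * **majority** — labelled members disagree; one labelled member is drawn
#'   uniformly at random `r` times and the group takes the majority class
#'   of the drawn labels (ties broken towards the lexicographically
#'   smallest class).
#' * **nearest-group** — no member is labelled; the group inherits the
#'   class of the most similar labelled group (see
#'   [nearest_labeled_group()]).
#'
#' @param groups An `"ec_groups"` tibble from [extract_groups()].
#' @param labels Label vector aligned with the original points
#'   (NA = unlabelled). Defaults to the labels recorded on `groups`.
#' @param r Number of random representative draws for mixed groups.
#' @param seed Integer seed for the draws.
#' @return A tibble with one row per group: `group_id`, `class`, `case`
#'   (`"unanimous"`, `"majority"` or `"nearest-group"`), `votes`
#'   (list-column of named draw tallies; empty for non-majority cases) and
#'   `source_group` (the donor group for nearest-group cases, else the
#'   group itself).
#' @export
assign_group_labels <- function(groups, labels = NULL, r = 100, seed = 1) {
  labels <- labels %||% attr(groups, "labels")
  if (is.null(labels)) abort("`labels` are required to label groups.")
  labels <- as.character(labels)
  if (!is.numeric(r) || length(r) != 1 || r < 1) {
    abort("`r` must be a single integer >= 1.")
  }
  if (all(is.na(labels))) {
    abort("no labelled points: at least one label is required.")
  }
  r <- as.integer(r)
  s <- nrow(groups)
  class <- character(s)
  case <- character(s)
  votes <- vector("list", s)
  source_group <- groups$group_id
  member_labels <- lapply(groups$members, function(m) {
    l <- labels[m]
    l[!is.na(l)]
  })
  withr::with_seed(seed, {
    for (i in seq_len(s)) {
      ml <- member_labels[[i]]
      votes[[i]] <- integer(0)
      if (length(ml) == 0) {
        case[i] <- "nearest-group"
        class[i] <- NA_character_
      } else if (length(unique(ml)) == 1) {
        case[i] <- "unanimous"
        class[i] <- ml[1]
      } else {
        case[i] <- "majority"
        draws <- sample(ml, r, replace = TRUE)
        tally <- table(draws)
        votes[[i]] <- setNames(as.integer(tally), names(tally))
        class[i] <- majority_label(draws)
      }
    }
  })
  # Case 3: fully unlabelled groups inherit from the nearest labelled group.
  labeled_ids <- groups$group_id[lengths(member_labels) > 0]
  for (i in which(case == "nearest-group")) {
    donor <- nearest_labeled_group(groups, groups$group_id[i],
                                   candidates = labeled_ids)
    class[i] <- class[match(donor, groups$group_id)]
    source_group[i] <- donor
  }
  tibble(
    group_id = groups$group_id,
    class = class,
    case = case,
    votes = votes,
    source_group = source_group
  )
}

#' Most similar labelled group
#'
#' Among candidate groups, returns the one whose representative vector has
#' the highest EC-space [similarity][ec_similarity] to the representative
#' of the query group. Ties are broken first towards the candidate with
#' more labelled members (more evidence), then towards the lowest group
#' id (determinism).
#'
#' @param groups An `"ec_groups"` tibble.
#' @param group_id The query group's id.
#' @param candidates Group ids to search among; defaults to all groups
#'   with at least one labelled member (requires a `n_labeled` column).
#' @return The id of the most similar candidate group.
#' @export
nearest_labeled_group <- function(groups, group_id, candidates = NULL) {
  if (is.null(candidates)) {
    if (!"n_labeled" %in% names(groups)) {
      abort("supply `candidates` or a grouping with an `n_labeled` column.")
    }
    candidates <- groups$group_id[groups$n_labeled > 0]
  }
  candidates <- setdiff(candidates, group_id)
  if (length(candidates) == 0) {
    abort("no labelled group available to classify from.")
  }
  rep_query <- groups$representative[[match(group_id, groups$group_id)]]
  idx <- match(candidates, groups$group_id)
  sim <- vapply(idx, function(j) {
    ec_similarity(rep_query, groups$representative[[j]])
  }, double(1))
  n_lab <- if ("n_labeled" %in% names(groups)) {
    groups$n_labeled[idx]
  } else {
    rep(0L, length(idx))
  }
  ord <- order(-sim, -n_lab, candidates)
  candidates[ord[1]]
}

#' Fit the group-based EC classifier and predict every point
#'
#' The full pipeline: transform labelled and unlabelled points jointly
#' into the EC space ([ec_transform()]), collapse identical rows into
#' groups ([extract_groups()]), label every group by the three-case rule
#' ([assign_group_labels()]), and propagate each group's class to all its
#' members. The method is transductive: unlabelled points shape the
#' clustering, and there is no out-of-sample prediction without
#' re-transforming.
#'
#' @inheritParams ec_transform
#' @param r Number of random representative draws for mixed groups.
#' @return An object of class `"grp_classifier_ec"`; use [tidy()] for the
#'   per-point predictions, [glance()] for a one-row model summary, and
#'   `$groups`, `$group_labels`, `$ec` for the intermediate objects.
#' @examples
#' sim <- make_clustered_data(n_points = 60, separation = 8,
#'                            unlabeled_fraction = 0.3, seed = 1)
#' fit <- fit_predict(sim$data, nmc = 6, r = 100, seed = 1)
#' head(tidy(fit))
#' glance(fit)
#' @export
fit_predict <- function(data, nmc, r = 100, seed = 1, nstart = 10,
                        iter_max = 300, init = c("plusplus", "random"),
                        standardize = FALSE, label_col = "class",
                        id_col = "point_id") {
  init <- match.arg(init)
  parts <- as_feature_parts(data, label_col = label_col, id_col = id_col)
  if (is.null(parts$labels)) {
    abort(sprintf("`data` must have a label column (`%s`).", label_col))
  }
  if (all(is.na(parts$labels))) {
    abort("no labelled points: at least one label is required.")
  }
  ec <- ec_transform(data, nmc = nmc, seed = seed, nstart = nstart,
                     iter_max = iter_max, init = init,
                     standardize = standardize, label_col = label_col,
                     id_col = id_col)
  groups <- extract_groups(ec)
  group_labels <- assign_group_labels(groups, r = r,
                                      seed = derive_seed(seed, 0L))
  gid_of_point <- integer(sum(groups$size))
  for (i in seq_len(nrow(groups))) {
    gid_of_point[groups$members[[i]]] <- groups$group_id[i]
  }
  gl <- group_labels[match(gid_of_point, group_labels$group_id), ]
  predictions <- tibble(
    point_id = ec$point_id,
    class_observed = parts$labels,
    class_pred = gl$class,
    group_id = gid_of_point,
    case = gl$case
  )
  structure(
    list(
      predictions = predictions,
      groups = groups,
      group_labels = group_labels,
      ec = ec,
      params = list(nmc = as.integer(nmc), r = as.integer(r),
                    seed = as.integer(seed), nstart = nstart,
                    iter_max = iter_max, init = init,
                    standardize = standardize)
    ),
    class = "grp_classifier_ec"
  )
}

#' @export
print.grp_classifier_ec <- function(x, ...) {
  p <- x$params
  cat("Group-based EC classifier\n")
  cat(sprintf("  points: %d   groups: %d   reduction ratio: %.3f\n",
              nrow(x$predictions), nrow(x$groups),
              reduction_ratio(x$groups)))
  cat(sprintf("  nmc: %d (EC dimension %d)   r: %d   seed: %d\n",
              p$nmc, p$nmc - 1L, p$r, p$seed))
  cat("  cases:",
      paste(sprintf("%s=%d", names(table(x$predictions$case)),
                    as.integer(table(x$predictions$case))),
            collapse = "  "), "\n")
  invisible(x)
}

#' @describeIn fit_predict Per-point predictions as a tibble
#'   (`point_id`, `class_observed`, `class_pred`, `group_id`, `case`).
#' @param x A `"grp_classifier_ec"` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.grp_classifier_ec <- function(x, ...) {
  x$predictions
}

#' @describeIn fit_predict One-row summary: point/group counts, reduction
#'   ratio, parameters, and training accuracy over the labelled points.
#' @exportS3Method generics::glance
glance.grp_classifier_ec <- function(x, ...) {
  lab <- !is.na(x$predictions$class_observed)
  tibble(
    n_points = nrow(x$predictions),
    n_labeled = sum(lab),
    n_groups = nrow(x$groups),
    reduction_ratio = reduction_ratio(x$groups),
    nmc = x$params$nmc,
    r = x$params$r,
    seed = x$params$seed,
    accuracy_labeled = mean(
      x$predictions$class_pred[lab] == x$predictions$class_observed[lab]
    )
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.grp_classifier_ec <- function(object, ...) {
  df <- object$predictions |>
    dplyr::count(.data$group_id, .data$case, name = "size")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$size, fill = .data$case
  )) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "group size", y = "number of groups",
                  fill = "labeling case") +
    ggplot2::theme_minimal()
}
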