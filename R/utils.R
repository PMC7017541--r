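# Internal helpers shared across modules.

# Deterministic per-task seed derived from a master seed and an integer tag.
# Kept inside [0, 2^31 - 1] so it is always a valid R integer seed; products
# stay below 2^53 so the double arithmetic is exact.
derive_seed <- function(seed, tag) {
  s <- as.double(seed) %% 2147483647
  as.integer((s * 48271 + as.double(tag) * 2654435) %% 2147483647)
}

# Split a feature table into the pieces the algorithms work with: a numeric
# matrix of feature values, point identifiers, and a label vector where NA
# marks an unlabelled point.
as_feature_parts <- function(data, label_col = "class", id_col = "point_id") {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("`data` must be a data frame with at least one row.")
  }
  data <- as_tibble(data)
  if (id_col %in% names(data)) {
    ids <- as.character(data[[id_col]])
    if (anyDuplicated(ids)) abort("point identifiers must be unique.")
  } else {
    ids <- as.character(seq_len(nrow(data)))
  }
  labels <- NULL
  if (label_col %in% names(data)) {
    labels <- as.character(data[[label_col]])
    labels[!is.na(labels) & labels == ""] <- NA_character_
  }
  feat_cols <- setdiff(names(data), c(label_col, id_col))
  values <- data[feat_cols]
  numeric_ok <- vapply(values, is.numeric, logical(1))
  if (length(feat_cols) == 0 || !all(numeric_ok)) {
    bad <- feat_cols[!numeric_ok]
    abort(paste0(
      "all feature columns must be numeric",
      if (length(bad)) paste0("; non-numeric: ", paste(bad, collapse = ", "))
    ))
  }
  values <- as.matrix(values)
  if (anyNA(values)) abort("feature values must not contain missing entries.")
  list(values = values, ids = ids, labels = labels)
}

# Majority vote with deterministic ties: the lexicographically smallest
# label among those tied at the maximum count wins.
majority_label <- function(x) {
  tab <- table(x)
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1]
}
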