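# Shared helpers: independent brute-force oracles and tiny data builders.

# O(n^2) grouping oracle: two rows belong together iff their pairwise
# similarity is exactly 1. Independent of extract_groups' hashing path.
brute_force_groups <- function(ec) {
  kcols <- grep("^k[0-9]+$", names(ec), value = TRUE)
  rows <- lapply(seq_len(nrow(ec)), function(i) {
    unname(vapply(kcols, function(cn) ec[[cn]][i], character(1)))
  })
  n <- length(rows)
  gid <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (!is.na(gid[i])) next
    next_id <- next_id + 1L
    gid[i] <- next_id
    for (j in seq_len(n)) {
      if (j > i && is.na(gid[j]) &&
          mean(rows[[i]] == rows[[j]]) == 1) {
        gid[j] <- next_id
      }
    }
  }
  unname(split(seq_len(n), gid))
}

# Random categorical matrix shaped like an EC transform output.
random_ec <- function(n, nmc, seed) {
  withr::with_seed(seed, {
    cols <- lapply(2:nmc, function(k) {
      paste0("c", sample.int(k, n, replace = TRUE) - 1L)
    })
    names(cols) <- paste0("k", 2:nmc)
    tibble::as_tibble(c(list(point_id = as.character(seq_len(n))), cols))
  })
}

# Two well-separated Gaussian blobs as a plain feature tibble.
two_blob_data <- function(n_per = 5, gap = 100, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(n_per * 2), n_per, 2),
      matrix(rnorm(n_per * 2) + gap, n_per, 2)
    )
  })
  tibble::tibble(x1 = x[, 1], x2 = x[, 2])
}

# Random valid confusion-matrix counts.
random_confusion <- function(seed) {
  withr::with_seed(seed, {
    counts <- sample.int(50, 4, replace = TRUE)
  })
  list(tp = counts[1], fp = counts[2], tn = counts[3], fn = counts[4])
}

# Expand confusion counts into aligned truth/pred label vectors.
confusion_to_labels <- function(cm, pos = "P", neg = "N") {
  truth <- c(rep(pos, cm$tp), rep(neg, cm$fp),
             rep(neg, cm$tn), rep(pos, cm$fn))
  pred <- c(rep(pos, cm$tp), rep(pos, cm$fp),
            rep(neg, cm$tn), rep(neg, cm$fn))
  list(truth = truth, pred = pred)
}

write_temp_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}
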