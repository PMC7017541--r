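#' Read RNA precursor sequences from a FASTA file
#'
#' Sequences are uppercased and DNA-style `T` is mapped to `U`; after
#' that, any character outside `{A, U, C, G}` is an error naming the
#' offending record, as are empty sequences and duplicate identifiers.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id: ", ids[duplicated(ids)][1]))
  }
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0) {
      abort(paste0("empty sequence for record: ", ids[i]))
    }
    if (grepl("[^AUCG]", seqs[i])) {
      abort(paste0("record ", ids[i],
                   " contains characters outside {A, U, C, G}"))
    }
  }
  tibble(id = ids, sequence = unname(seqs))
}

#' Normalized k-mer frequencies of one sequence
#'
#' Counts each of the `4^k` length-k words over `{A, C, G, U}` among the
#' `L - k + 1` sliding windows of the sequence and divides by the
#' sequence length `L` (not by the window count; both conventions exist,
#' this one normalizes by length). A `k` larger than the sequence gives
#' an all-zero vector.
#'
#' @param sequence A single RNA sequence string (`A`/`U`/`C`/`G`; `T`
#'   accepted and mapped to `U`).
#' @param k Word length (>= 1).
#' @return A named numeric vector over the `4^k` k-mers in lexicographic
#'   (A < C < G < U) order.
#' @examples
#' kmer_frequencies("AUCG", 2)[c("AU", "UC", "CG")]  # each 0.25
#' @export
kmer_frequencies <- function(sequence, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort("`k` must be a single integer >= 1.")
  }
  k <- as.integer(k)
  sequence <- gsub("T", "U", toupper(sequence), fixed = TRUE)
  if (grepl("[^AUCG]", sequence)) {
    abort("sequence contains characters outside {A, U, C, G}")
  }
  L <- nchar(sequence)
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "U"), k)
  if (k > L) {
    return(setNames(numeric(length(kmers)), kmers))
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::RNAString(sequence), width = k
  )
  (counts / L)[kmers]
}

#' Build a classifier-ready feature table from sequences
#'
#' Concatenates [kmer_frequencies()] blocks for every `k` in `k_set`
#' (ascending, k-mers lexicographic within each block) into one numeric
#' feature table, one row per input record in input order. An optional
#' label table is joined on `id`; records without a label become
#' unlabelled points.
#'
#' @param records A tibble with `id` and `sequence` columns, as returned
#'   by [read_fasta()].
#' @param k_set Integer vector of word lengths; default `1:3`.
#' @param labels Optional data frame with columns `id` and `class`.
#' @return A tibble with `point_id`, `class` (NA where unlabelled) and
#'   one numeric column per k-mer.
#' @examples
#' recs <- tibble::tibble(id = c("s1", "s2"),
#'                        sequence = c("AUCG", "GGGG"))
#' featurize(recs, k_set = 1:2)
#' @export
featurize <- function(records, k_set = 1:3, labels = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must be a non-empty data frame.")
  }
  if (anyDuplicated(records$id)) {
    abort(paste0("duplicate sequence id: ",
                 records$id[duplicated(records$id)][1]))
  }
  k_set <- sort(unique(as.integer(k_set)))
  feat <- lapply(records$sequence, function(s) {
    unlist(lapply(k_set, function(k) kmer_frequencies(s, k)))
  })
  mat <- do.call(rbind, feat)
  out <- bind_cols(tibble(point_id = as.character(records$id)),
                   as_tibble(mat))
  cls <- rep(NA_character_, nrow(out))
  if (!is.null(labels)) {
    stopifnot(all(c("id", "class") %in% names(labels)))
    m <- match(out$point_id, as.character(labels$id))
    cls[!is.na(m)] <- as.character(labels$class)[m[!is.na(m)]]
  }
  out$class <- cls
  select(out, "point_id", "class", dplyr::everything())
}
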