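#' Shannon entropy of a class labeling
#'
#' `-sum(p_c * log2(p_c))` over the class frequencies, in bits. Zero when
#' all labels agree; `log2(K)` for K perfectly balanced classes.
#'
#' @param labels Class labels (any type coercible to factor).
#' @return Entropy in bits.
#' @examples
#' class_entropy(c("a", "a", "b", "b"))  # 1
#' @export
class_entropy <- function(labels) {
  if (length(labels) < 1L) stop("need at least one label")
  p <- tabulate(as.factor(labels))
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

#' Best binary split of one gene's expression values
#'
#' C4.5-style handling of a continuous attribute: candidate thresholds are
#' the midpoints between consecutive distinct sorted values; the threshold
#' maximizing the information gain of the induced two-way partition is
#' returned together with that gain and the partition's split information
#' (the entropy of the left/right sizes). A constant gene has no candidate
#' split and returns gain 0.
#'
#' @param values Numeric expression of one gene across samples.
#' @param labels Class labels, aligned with `values`.
#' @return List with `threshold` (NA for a constant gene), `gain`,
#'   `split_info`, all in bits. Ties in gain keep the smallest threshold.
#' @examples
#' best_split_gain(1:6, rep(c("A", "B"), each = 3))  # threshold 3.5, gain 1
#' @export
best_split_gain <- function(values, labels) {
  if (length(values) != length(labels))
    stop("values and labels must be aligned")
  y <- as.factor(labels)
  n <- length(values)
  ord <- order(values)
  v <- values[ord]
  yo <- as.integer(y)[ord]
  # split allowed only between distinct consecutive values
  cut_after <- which(v[-n] < v[-1])
  if (length(cut_after) == 0L)
    return(list(threshold = NA_real_, gain = 0, split_info = 0))

  k <- nlevels(y)
  # cumulative class counts after each sorted sample
  cum <- apply(outer(yo, seq_len(k), "=="), 2L, cumsum)
  cum <- matrix(cum, nrow = n)

  h_total <- class_entropy(y)
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)

  left <- cum[cut_after, , drop = FALSE]
  n_left <- cut_after
  right <- matrix(cum[n, ], nrow = length(cut_after), ncol = k,
                  byrow = TRUE) - left
  n_right <- n - n_left
  h_left <- -rowSums(plogp(left / n_left))
  h_right <- -rowSums(plogp(right / n_right))
  gain <- h_total - (n_left * h_left + n_right * h_right) / n
  split_info <- -(plogp(n_left / n) + plogp(n_right / n))

  best <- which.max(gain)  # first maximum: smallest threshold on ties
  i <- cut_after[best]
  list(threshold = (v[i] + v[i + 1L]) / 2,
       gain = gain[best],
       split_info = split_info[best])
}

#' Gain ratio of one gene
#'
#' Information gain of the gene's best binary split normalized by the
#' split's own entropy. Zero when the gene is constant, when the best gain
#' is 0, or when the split information is 0 (all samples on one side).
#' Because the score depends only on the ordering of the values, it is
#' invariant to monotone transformations of the expression scale.
#'
#' @inheritParams best_split_gain
#' @return Non-negative score; 1 for a perfectly class-separating balanced
#'   split.
#' @export
gain_ratio <- function(values, labels) {
  s <- best_split_gain(values, labels)
  if (s$split_info <= 0 || s$gain <= 0) return(0)
  s$gain / s$split_info
}

#' Rank all genes by gain ratio
#'
#' @param dataset An [expression_dataset()].
#' @return A data.frame with one row per gene, ordered by decreasing score
#'   (ties stable in original gene order): columns `gene`, `score`,
#'   `threshold`, `rank`.
#' @export
rank_genes <- function(dataset) {
  y <- dataset$labels
  scores <- vapply(seq_len(n_genes(dataset)), function(j) {
    s <- best_split_gain(dataset$x[, j], y)
    gr <- if (s$split_info <= 0 || s$gain <= 0) 0 else s$gain / s$split_info
    c(gr, s$threshold)
  }, numeric(2))
  ord <- order(-scores[1L, ])  # radix order: stable on ties
  data.frame(
    gene = dataset$genes[ord],
    score = scores[1L, ord],
    threshold = scores[2L, ord],
    rank = seq_len(ncol(scores)),
    stringsAsFactors = FALSE
  )
}

#' Pre-select the top-ranked genes by gain ratio
#'
#' The published pipeline pre-reduces the expression matrix to the 500
#' top-ranked genes before swarm search; the fitness' total gene count n
#' then refers to the reduced set.
#'
#' @param dataset An [expression_dataset()].
#' @param k Number of genes to keep (default 500); `k >= n_genes` keeps
#'   all.
#' @return A list with `dataset` (the reduced `expr_dataset`, genes in
#'   original order) and `ranking` (the full [rank_genes()] table).
#' @export
select_top_genes <- function(dataset, k = 500L) {
  stopifnot(k >= 1L)
  ranking <- rank_genes(dataset)
  keep_ids <- ranking$gene[seq_len(min(k, nrow(ranking)))]
  keep <- dataset$genes %in% keep_ids
  out <- dataset
  out$x <- dataset$x[, keep, drop = FALSE]
  out$genes <- dataset$genes[keep]
  list(dataset = out, ranking = ranking)
}

#' Write a gene ranking as delimited text
#'
#' Columns: gene id, score, threshold, rank.
#'
#' @param ranking A data.frame from [rank_genes()].
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @export
write_ranking <- function(ranking, path, sep = "\t") {
  utils::write.table(ranking, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
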