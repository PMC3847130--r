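#' Synthetic labeled expression data with planted informative genes
#'
#' Generates a samples-by-genes Gaussian expression matrix emulating the
#' shape of benchmark microarray sets (thousands of genes, tens to
#' hundreds of samples, 2-11 classes, a small informative subset against
#' noisy background). Background genes are independent zero-mean Gaussians
#' with standard deviation `noise_sd`. Each of the `n_informative` planted
#' genes receives a class-dependent mean offset: samples of class c
#' (0-based class index) are shifted by `c * effect_size * noise_sd`, so a
#' single planted gene separates all classes once the effect size clearly
#' exceeds the noise. Class sizes are as balanced as divisibility allows
#' unless explicit `class_weights` are given.
#'
#' The defaults are the desk-scale study conditions used throughout the
#' package's tests: 30 samples, 100 genes, 3 classes, 5 planted genes with
#' effect size 5.
#'
#' @param n_samples Number of samples (at least `2 * n_classes`).
#' @param n_genes Total number of genes.
#' @param n_classes Number of classes (at least 2).
#' @param n_informative Number of planted informative genes
#'   (`<= n_genes`).
#' @param effect_size Class-mean shift per class step, in units of
#'   `noise_sd`; 0 makes the planted genes indistinguishable from
#'   background.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param class_weights Optional positive weights, one per class, for
#'   imbalanced designs; default balanced.
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @return An object of class `synthetic_dataset`: list with `dataset`
#'   (an [expression_dataset()]) and `informative` (character ids of the
#'   planted genes).
#' @examples
#' d <- synthetic_dataset(seed = 1)
#' d$informative
#' @export
synthetic_dataset <- function(n_samples = 30L,
                              n_genes = 100L,
                              n_classes = 3L,
                              n_informative = 5L,
                              effect_size = 5,
                              noise_sd = 1,
                              class_weights = NULL,
                              seed = NULL) {
  n_samples <- as.integer(n_samples)
  n_genes <- as.integer(n_genes)
  n_classes <- as.integer(n_classes)
  n_informative <- as.integer(n_informative)
  stopifnot(
    n_classes >= 2L,
    n_samples >= 2L * n_classes,
    n_informative >= 0L, n_informative <= n_genes,
    effect_size >= 0, noise_sd > 0
  )
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (is.null(class_weights)) {
    sizes <- rep(n_samples %/% n_classes, n_classes)
    extra <- n_samples %% n_classes
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  } else {
    stopifnot(length(class_weights) == n_classes, all(class_weights > 0))
    sizes <- round(n_samples * class_weights / sum(class_weights))
    sizes[n_classes] <- n_samples - sum(sizes[-n_classes])
    if (any(sizes < 1L)) stop("class_weights leave a class empty")
  }
  class_index <- rep(seq_len(n_classes) - 1L, times = sizes)  # 0-based
  labels <- factor(paste0("C", class_index + 1L),
                   levels = paste0("C", seq_len(n_classes)))

  x <- matrix(stats::rnorm(n_samples * n_genes, sd = noise_sd),
              nrow = n_samples, ncol = n_genes)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  colnames(x) <- gene_ids
  rownames(x) <- sprintf("s%03d", seq_len(n_samples))

  informative <- sort(sample.int(n_genes, n_informative))
  for (j in informative)
    x[, j] <- x[, j] + class_index * effect_size * noise_sd

  structure(
    list(dataset = expression_dataset(x, labels),
         informative = gene_ids[informative]),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  print(x$dataset)
  cat("Planted informative genes:",
      paste(x$informative, collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic dataset plus its ground truth
#'
#' Writes the expression matrix in the package's delimited format (see
#' [write_expression_matrix()]) and the planted gene ids, one per line, to
#' `truth_path`.
#'
#' @param synth A `synthetic_dataset`.
#' @param path Expression matrix output file.
#' @param truth_path Ground-truth gene-id list output file.
#' @param sep Field separator.
#' @export
write_synthetic_dataset <- function(synth, path, truth_path, sep = "\t") {
  write_expression_matrix(synth$dataset, path, sep = sep)
  writeLines(synth$informative, truth_path)
  invisible(path)
}
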