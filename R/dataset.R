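#' Labeled gene-expression dataset
#'
#' Container for a samples-by-genes real-valued expression matrix with one
#' categorical class label per sample. This is the input to the gain-ratio
#' filter and to the swarm optimizers.
#'
#' @param x Numeric matrix, samples in rows, genes in columns. Column names
#'   are used as gene identifiers and row names as sample identifiers;
#'   defaults (`g1..gn`, `s1..sN`) are generated when absent.
#' @param labels Class labels, one per sample (coerced to factor). At least
#'   two classes are required.
#' @return An object of class `expr_dataset`: a list with elements `x`
#'   (the matrix), `labels` (factor), `genes`, `samples`.
#' @examples
#' x <- matrix(rnorm(20), nrow = 4)
#' d <- expression_dataset(x, labels = c("a", "a", "b", "b"))
#' n_genes(d)
#' @export
expression_dataset <- function(x, labels) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix (samples x genes)")
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  if (length(labels) != nrow(x))
    stop("need exactly one label per sample (row): got ", length(labels),
         " labels for ", nrow(x), " samples")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L)
    stop("need at least two classes, got ", nlevels(labels))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("g", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x)))
    stop("duplicate gene identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (is.null(rownames(x)))
    rownames(x) <- paste0("s", seq_len(nrow(x)))
  structure(
    list(x = x, labels = labels, genes = colnames(x), samples = rownames(x)),
    class = "expr_dataset"
  )
}

#' @rdname expression_dataset
#' @param dataset An `expr_dataset`.
#' @export
n_genes <- function(dataset) ncol(dataset$x)

#' @rdname expression_dataset
#' @export
n_samples <- function(dataset) nrow(dataset$x)

#' @export
print.expr_dataset <- function(x, ...) {
  cat("Gene-expression dataset:", n_samples(x), "samples x",
      n_genes(x), "genes,", nlevels(x$labels), "classes\n")
  cat("Class sizes:",
      paste(sprintf("%s=%d", levels(x$labels), tabulate(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a dataset to the genes selected by a binary position
#'
#' Keeps exactly the genes whose bits are 1, preserving gene order. A bit
#' vector is the particle-position encoding: bit d set means gene d is in
#' the candidate subset.
#'
#' @param dataset An [expression_dataset()].
#' @param position Binary vector (0/1) of length `n_genes(dataset)`.
#' @return An `expr_dataset` with the selected genes only. With an all-zero
#'   position the result has zero gene columns (the caller is expected to
#'   treat an empty subset specially, see [fitness_value()]).
#' @export
subset_genes <- function(dataset, position) {
  position <- check_position(position, n_genes(dataset))
  keep <- position == 1L
  out <- dataset
  out$x <- dataset$x[, keep, drop = FALSE]
  out$genes <- dataset$genes[keep]
  out
}

# validate a 0/1 position vector of expected length
check_position <- function(position, n) {
  position <- as.integer(position)
  if (length(position) != n)
    stop("position length ", length(position), " does not match gene count ", n)
  if (anyNA(position) || !all(position %in% c(0L, 1L)))
    stop("position must contain only 0/1 bits")
  position
}
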