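#' Leave-one-out cross-validated accuracy of the selected-gene SVM
#'
#' For every sample, a support vector machine is trained on the remaining
#' N - 1 samples restricted to the selected genes and used to predict the
#' held-out sample; the accuracy is the fraction of correct predictions.
#' The classifier follows the published setup: RBF kernel, cost C = 1,
#' gamma = 1 / k with k the number of selected genes, and one-against-one
#' multiclass voting. No feature scaling is applied by default
#' (`scale = TRUE` standardizes inside the SVM for users with raw
#' real-world intensities).
#'
#' The folds are run as an explicit loop. (libsvm's built-in
#' cross-validation is not used: its one-against-one vote ties are broken
#' in the order of an internal random fold permutation, so its
#' leave-one-out accuracy is not reproducible call to call.) A training
#' fold that contains a single class — possible only in degenerate tiny
#' designs — predicts the only class it has seen.
#'
#' @param dataset An [expression_dataset()].
#' @param position Optional binary 0/1 vector selecting genes; `NULL` uses
#'   all genes. At least one gene must be selected.
#' @param cost SVM cost parameter C.
#' @param scale Standardize features inside the SVM (default `FALSE`).
#' @param classifier Optional pluggable classifier: a list with functions
#'   `fit(x, y)` returning a model and `predict(model, newx)` returning
#'   labels. When supplied, the explicit fold loop is used with it instead
#'   of the SVM.
#' @return Accuracy in \[0, 1\].
#' @examples
#' d <- synthetic_dataset(n_samples = 20, n_genes = 10, n_classes = 2,
#'                        n_informative = 2, effect_size = 8, seed = 1)
#' loocv_accuracy(d$dataset)
#' @export
loocv_accuracy <- function(dataset, position = NULL, cost = 1,
                           scale = FALSE, classifier = NULL) {
  if (!is.null(position)) dataset <- subset_genes(dataset, position)
  x <- dataset$x
  y <- dataset$labels
  n_sel <- ncol(x)
  if (n_sel < 1L) stop("empty gene subset: no genes selected")
  n <- nrow(x)
  if (n < 2L) stop("need at least two samples for leave-one-out")

  if (is.null(classifier))
    classifier <- svm_classifier(cost = cost, gamma = 1 / n_sel,
                                 scale = scale)

  correct <- 0L
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2L) {
      pred <- levels(ytr)[1L]
    } else {
      model <- classifier$fit(x[-i, , drop = FALSE], ytr)
      pred <- as.character(classifier$predict(model, x[i, , drop = FALSE]))
    }
    correct <- correct + (pred == as.character(y[i]))
  }
  correct / n
}

#' RBF-kernel SVM as a pluggable classifier
#'
#' Returns the fit/predict pair used by [loocv_accuracy()]'s explicit fold
#' loop; exported so alternative classifiers can follow the same contract.
#'
#' @param cost Cost parameter C.
#' @param gamma RBF kernel width; the selection pipeline uses 1 / k with k
#'   the number of selected genes.
#' @param scale Standardize features inside the SVM.
#' @return A list with elements `fit(x, y)` and `predict(model, newx)`.
#' @export
svm_classifier <- function(cost = 1, gamma = NULL, scale = FALSE) {
  list(
    fit = function(x, y) {
      g <- if (is.null(gamma)) 1 / ncol(x) else gamma
      e1071::svm(x, y, kernel = "radial", cost = cost, gamma = g,
                 scale = scale)
    },
    predict = function(model, newx) stats::predict(model, newx)
  )
}

#' Combined fitness of a gene subset
#'
#' `fitness = w1 * A + w2 * (n - R) / n` where A is the LOOCV accuracy of
#' the subset, R the number of selected genes and n the total gene count;
#' w1 weights accuracy and w2 = 1 - w1 rewards small subsets. The empty
#' subset (R = 0) receives a fixed fitness (default 0) instead of the
#' literal formula value w2, which would otherwise reward selecting
#' nothing.
#'
#' @param accuracy LOOCV accuracy A in \[0, 1\] (ignored when `n_selected`
#'   is 0).
#' @param n_selected Number of selected genes R.
#' @param n Total number of genes.
#' @param w1,w2 Priority weights; must satisfy `w1 + w2 = 1`.
#' @param empty_value Fitness of the empty subset.
#' @return Fitness in \[0, 1\] (given `empty_value` in \[0, 1\]).
#' @examples
#' fitness_value(accuracy = 0.9, n_selected = 50, n = 500)  # 0.9
#' @export
fitness_value <- function(accuracy, n_selected, n, w1 = 0.8, w2 = 1 - w1,
                          empty_value = 0) {
  stopifnot(n >= 1, abs(w1 + w2 - 1) < 1e-12)
  if (n_selected > n)
    stop("inconsistent state: ", n_selected, " genes selected out of ", n)
  if (n_selected == 0L) return(empty_value)
  stopifnot(accuracy >= 0, accuracy <= 1)
  w1 * accuracy + w2 * (n - n_selected) / n
}

# Evaluate one position: accuracy + combined fitness, with a per-run cache
# keyed by the selected-gene index set. The classifier may touch the R RNG
# internally, so the global RNG state is saved and restored around the
# evaluation: the swarm's own draw sequence never depends on the fitness
# path taken (cache hit, fast path, fold loop).
evaluate_position <- function(dataset, position, config, cache = NULL) {
  r <- sum(position)
  n <- length(position)
  key <- if (!is.null(cache))
    paste0("k", paste(which(position == 1L), collapse = ","))
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  if (r == 0L) {
    out <- list(fitness = config$empty_subset_fitness, accuracy = NA_real_,
                n_selected = 0L)
  } else {
    rng <- get0(".Random.seed", envir = globalenv())
    acc <- loocv_accuracy(dataset, position, cost = config$svm_cost,
                          scale = config$svm_scale)
    if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv())
    out <- list(
      fitness = fitness_value(acc, r, n, w1 = config$w1, w2 = config$w2,
                              empty_value = config$empty_subset_fitness),
      accuracy = acc, n_selected = r
    )
  }
  if (!is.null(cache)) cache[[key]] <- out
  out
}
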