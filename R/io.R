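#' Read a labeled expression matrix from delimited text
#'
#' Canonical layout: one header row with a sample-id column, the gene ids,
#' and a designated label column; then one row per sample. A transposed
#' layout (genes as rows, samples as columns, labels in a final row named
#' by `label_col`) is supported via `genes_as_rows = TRUE`. Missing or
#' non-numeric expression cells, a missing label column and duplicate gene
#' ids are load errors reported with row/column context.
#'
#' @param path Input file.
#' @param sep Field separator; default tab, comma accepted.
#' @param label_col Name of the label column (default `"class"`).
#' @param genes_as_rows Set `TRUE` for the transposed layout.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, sep = "\t", label_col = "class",
                                   genes_as_rows = FALSE) {
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (genes_as_rows) {
    if (!label_col %in% rownames(df))
      stop("no label row named '", label_col, "' in ", path)
    labels <- unlist(df[label_col, ], use.names = FALSE)
    genes <- rownames(df)[rownames(df) != label_col]
    df <- df[rownames(df) != label_col, , drop = FALSE]
    samples <- colnames(df)
    x <- t(as.matrix(as.data.frame(lapply(df, as.numeric))))
    dimnames(x) <- list(samples, NULL)
  } else {
    if (!label_col %in% colnames(df))
      stop("no label column named '", label_col, "' in ", path)
    labels <- df[[label_col]]
    genes <- colnames(df)[colnames(df) != label_col]
    df <- df[, colnames(df) != label_col, drop = FALSE]
    samples <- rownames(df)
    x <- as.matrix(df)
  }
  if (anyDuplicated(genes))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (!is.numeric(x) || anyNA(x)) {
    bad <- which(is.na(suppressWarnings(apply(x, 2, as.numeric))),
                 arr.ind = TRUE)
    if (length(bad))
      stop("missing or non-numeric expression value at sample '",
           samples[bad[1, 1]], "', gene '", genes[bad[1, 2]], "' in ", path)
    stop("expression matrix in ", path, " is not numeric")
  }
  if (anyNA(labels) || any(labels == ""))
    stop("missing class label for sample '",
         samples[which(is.na(labels) | labels == "")[1]], "' in ", path)
  colnames(x) <- genes
  expression_dataset(x, labels)
}

#' Write a labeled expression matrix as delimited text
#'
#' Inverse of [read_expression_matrix()]'s canonical layout: a `sample`
#' id column, one column per gene, and the label column last.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output file.
#' @param sep Field separator.
#' @param label_col Name for the label column.
#' @export
write_expression_matrix <- function(dataset, path, sep = "\t",
                                    label_col = "class") {
  df <- as.data.frame(dataset$x, check.names = FALSE)
  df[[label_col]] <- as.character(dataset$labels)
  df <- cbind(sample = dataset$samples, df)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Repeated independent optimizer runs with best/average/SD aggregation
#'
#' Runs the optimizer `n_runs` times with per-run seeds derived from the
#' master seed (`config$seed + run - 1`, recorded per row, so any single
#' run can be reproduced alone) and aggregates the three reported
#' criteria: LOOCV accuracy, number of selected genes, and runtime. "Best"
#' is the highest accuracy, the smallest subset, and the shortest runtime
#' respectively.
#'
#' @param dataset An [expression_dataset()].
#' @param config A [swarm_config()] with a non-NULL master `seed`.
#' @param variant `"epso"` or `"bpso"`.
#' @param n_runs Number of independent runs (published protocol: 10).
#' @return An object of class `aggregate_report`: list with `per_run`
#'   (data.frame: run, seed, accuracy, n_genes, runtime_s), `summary`
#'   (data.frame: metric, best, average, sd), `runs` (the `swarm_run`
#'   objects), `variant`.
#' @export
run_repeated <- function(dataset, config, variant = c("epso", "bpso"),
                         n_runs = 10L) {
  variant <- match.arg(variant)
  n_runs <- as.integer(n_runs)
  stopifnot(n_runs >= 1L)
  if (is.null(config$seed))
    stop("run_repeated needs a master seed in `config$seed`")
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    runs[[r]] <- run_swarm(dataset, cfg, variant)
  }
  per_run <- data.frame(
    run = seq_len(n_runs),
    seed = config$seed + seq_len(n_runs) - 1L,
    accuracy = vapply(runs, `[[`, numeric(1), "gbest_accuracy"),
    n_genes = vapply(runs, `[[`, numeric(1), "gbest_n_genes"),
    runtime_s = vapply(runs, `[[`, numeric(1), "elapsed")
  )
  summary <- data.frame(
    metric = c("accuracy", "n_genes", "runtime_s"),
    best = c(max(per_run$accuracy), min(per_run$n_genes),
             min(per_run$runtime_s)),
    average = c(mean(per_run$accuracy), mean(per_run$n_genes),
                mean(per_run$runtime_s)),
    sd = c(stats::sd(per_run$accuracy), stats::sd(per_run$n_genes),
           stats::sd(per_run$runtime_s))
  )
  if (n_runs == 1L) summary$sd <- 0
  structure(list(per_run = per_run, summary = summary, runs = runs,
                 variant = variant),
            class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat(sprintf("%s: %d independent runs\n", toupper(x$variant),
              nrow(x$per_run)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s best %.2f   Average +/- S.D. %.2f +/- %.2f\n",
                s$metric[i], s$best[i], s$average[i], s$sd[i]))
  invisible(x)
}

#' Write an aggregation report as delimited text
#'
#' Per-run rows followed by best/average/sd rows, recomputable from the
#' per-run values.
#'
#' @param report An `aggregate_report`.
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_report <- function(report, path, sep = "\t") {
  per <- report$per_run
  per$run <- as.character(per$run)
  s <- report$summary
  stat_rows <- data.frame(
    run = c("best", "average", "sd"),
    seed = NA_integer_,
    accuracy = c(s$best[1], s$average[1], s$sd[1]),
    n_genes = c(s$best[2], s$average[2], s$sd[2]),
    runtime_s = c(s$best[3], s$average[3], s$sd[3])
  )
  utils::write.table(rbind(per, stat_rows), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-run report and recompute its aggregate statistics
#'
#' @param path A file written by [write_report()] (only the numbered
#'   per-run rows are used; statistics are recomputed).
#' @param sep Field separator.
#' @return An `aggregate_report` (without the `runs` objects).
#' @export
read_report <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  per <- df[grepl("^[0-9]+$", df$run), , drop = FALSE]
  per$run <- as.integer(per$run)
  summary <- data.frame(
    metric = c("accuracy", "n_genes", "runtime_s"),
    best = c(max(per$accuracy), min(per$n_genes), min(per$runtime_s)),
    average = c(mean(per$accuracy), mean(per$n_genes),
                mean(per$runtime_s)),
    sd = if (nrow(per) == 1L) rep(0, 3) else
      c(stats::sd(per$accuracy), stats::sd(per$n_genes),
        stats::sd(per$runtime_s))
  )
  structure(list(per_run = per, summary = summary, runs = NULL,
                 variant = "unknown"),
            class = "aggregate_report")
}
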