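# Independent oracles, kept deliberately naive: they re-derive every
# quantity from first principles rather than reusing package internals.

# entropy of a count vector
oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# gain ratio by brute force: enumerate every admissible threshold,
# recompute all entropies from explicit partitions
oracle_gain_ratio <- function(values, labels) {
  labels <- as.factor(labels)
  h_total <- oracle_entropy(table(labels))
  thresholds <- sort(unique(values))
  if (length(thresholds) < 2) return(0)
  cands <- (thresholds[-1] + thresholds[-length(thresholds)]) / 2
  best_gain <- 0
  best_si <- 0
  for (thr in cands) {
    left <- values <= thr
    n_l <- sum(left); n_r <- sum(!left)
    h <- (n_l * oracle_entropy(table(labels[left])) +
          n_r * oracle_entropy(table(labels[!left]))) / length(values)
    gain <- h_total - h
    if (gain > best_gain) {
      best_gain <- gain
      best_si <- oracle_entropy(c(n_l, n_r))
    }
  }
  if (best_si <= 0 || best_gain <= 0) return(0)
  best_gain / best_si
}

# leave-one-out accuracy by an explicit fold-by-fold loop around e1071,
# mirroring the published classifier settings
oracle_loocv <- function(x, y, cost = 1) {
  y <- as.factor(y)
  n <- nrow(x)
  correct <- 0L
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2L) {
      pred <- levels(ytr)[1L]
    } else {
      fit <- e1071::svm(x[-i, , drop = FALSE], ytr, kernel = "radial",
                        cost = cost, gamma = 1 / ncol(x), scale = FALSE)
      pred <- as.character(predict(fit, x[i, , drop = FALSE]))
    }
    correct <- correct + (pred == as.character(y[i]))
  }
  correct / n
}
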