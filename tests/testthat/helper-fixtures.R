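# Shared fixtures and independent oracles used across test files.

# Small expression dataset with the full ICR panel plus a few extras.
make_panel_dataset <- function(n = 12, seed = 101, cohort_id = "test") {
  set.seed(seed)
  genes <- c(icr_panel(), "GAPDH", "ACTB", "TP53")
  m <- matrix(rnorm(length(genes) * n, 7, 1), length(genes), n,
              dimnames = list(genes, sprintf("s%02d", seq_len(n))))
  expression_dataset(m, cohort_id = cohort_id)
}

# Two well-separated Gaussian blobs in `p` dimensions (features x samples).
make_two_blobs <- function(n_per = 10, p = 5, sep = 10, seed = 7) {
  set.seed(seed)
  x <- cbind(matrix(rnorm(p * n_per, 0, 1), p),
             matrix(rnorm(p * n_per, sep, 1), p))
  colnames(x) <- sprintf("b%02d", seq_len(2 * n_per))
  list(x = x, truth = rep(1:2, each = n_per))
}

# Tiny raw-count object built by hand.
make_tiny_raw <- function(counts_endo, neg = c(4, 9), hk = c(50, 50),
                          pos = c(100, 100)) {
  # counts_endo: matrix endo-probes x samples; control counts identical
  # across samples unless overridden
  ns <- ncol(counts_endo)
  m2 <- rbind(counts_endo,
              matrix(neg, length(neg), ns),
              matrix(hk, length(hk), ns),
              matrix(pos, length(pos), ns))
  rownames(m2) <- c(sprintf("E%d", seq_len(nrow(counts_endo))),
                    sprintf("N%d", seq_along(neg)),
                    sprintf("H%d", seq_along(hk)),
                    sprintf("P%d", seq_along(pos)))
  colnames(m2) <- sprintf("s%d", seq_len(ns))
  raw_counts(m2, c(rep("endogenous", nrow(counts_endo)),
                   rep("negative", length(neg)),
                   rep("housekeeping", length(hk)),
                   rep("positive", length(pos))))
}

# Independent closed-form two-sided hypergeometric p for a 2x2 table
# [[a, b], [c, d]] (probability-mass ordering), used as the Fisher oracle.
hyper_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(xs, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force greedy Ward agglomeration oracle: at each step merge the pair
# of clusters whose merge minimizes the increase in total within-cluster
# sum of squares. Returns the partition at each k from n down to 1.
ward_oracle_partitions <- function(x) {
  # x: features x samples
  n <- ncol(x)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  labels <- seq_len(n)
  delta_sse <- function(i, j) {
    ci <- rowMeans(x[, clusters[[i]], drop = FALSE])
    cj <- rowMeans(x[, clusters[[j]], drop = FALSE])
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    ni * nj / (ni + nj) * sum((ci - cj)^2)
  }
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- delta_sse(i, j)
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    labels <- integer(n)
    for (g in seq_along(clusters)) labels[clusters[[g]]] <- g
    partitions[[length(clusters)]] <- labels
  }
  partitions
}
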