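#' Consensus clustering configuration
#'
#' Parameters of the resampling-based classifier: `repetitions` resamples of
#' `pItem` of the samples (without replacement), inner agglomerative
#' clustering with the Ward.D2 criterion cut at `k`, and a final "outer"
#' complete-linkage clustering of `1 - consensus`.
#'
#' @param repetitions number of resampling repetitions (default 5000).
#' @param pItem fraction of samples drawn in each repetition, in (0, 1].
#' @param k number of clusters (>= 2; default 4).
#' @param inner_distance `"euclidean"` (default; the metric under which the
#'   Ward criterion is defined) or `"pearson"` (1 - Pearson correlation).
#' @param inner_linkage,outer_linkage hclust method names; defaults
#'   `"ward.D2"` and `"complete"`. Ward.D2 applies the Lance-Williams update
#'   to squared distances with input distances NOT pre-squared by the caller
#'   (the D2 convention) - stated because the ward.D/ward.D2 discrepancy
#'   silently changes clusters.
#' @param seed integer seed driving the resampling stream.
#' @return List of class `consensus_config`.
#' @export
consensus_config <- function(repetitions = 5000L, pItem = 0.8, k = 4L,
                             inner_distance = c("euclidean", "pearson"),
                             inner_linkage = "ward.D2",
                             outer_linkage = "complete", seed = 1L) {
  inner_distance <- match.arg(inner_distance)
  repetitions <- as.integer(repetitions)
  k <- as.integer(k)
  if (repetitions < 1L) stop("repetitions must be >= 1")
  if (pItem <= 0 || pItem > 1) stop("pItem must be in (0, 1]")
  if (k < 2L) stop("k must be >= 2")
  structure(list(repetitions = repetitions, pItem = pItem, k = k,
                 inner_distance = inner_distance,
                 inner_linkage = inner_linkage,
                 outer_linkage = outer_linkage, seed = as.integer(seed)),
            class = "consensus_config")
}

sample_distance <- function(x, method) {
  # x: features x samples; distance between sample columns
  if (method == "euclidean") {
    stats::dist(t(x))
  } else {
    stats::as.dist(1 - stats::cor(x))
  }
}

#' Consensus clustering of samples on a feature panel
#'
#' For each repetition, draws `ceiling(pItem * n)` samples without
#' replacement, clusters them (Ward.D2 on the inner distance, cut at `k`),
#' and accumulates per-pair co-clustering and co-sampling counts. The
#' consensus matrix entry for a pair is co-clustered / co-sampled; pairs
#' never co-sampled (possible at very low repetition counts) are set to 0.5,
#' maximally uncertain, and their count is retained in `co_sample_counts`.
#' Final labels come from complete-linkage clustering of `1 - consensus`
#' cut at `k`. Resampling indexes samples in sorted sample-ID order, so the
#' result is invariant to input column order.
#'
#' @param x numeric matrix, features x samples (for the ICR classifier the
#'   20 panel genes), with sample IDs as column names.
#' @param config a [consensus_config()].
#' @return List of class `consensus_result`: `consensus_matrix`,
#'   `co_sample_counts`, `labels` (integer cluster per sample, input order),
#'   and the `config` with resolved settings.
#' @export
consensus_cluster <- function(x, config = consensus_config()) {
  stopifnot(is.matrix(x), is.numeric(x), inherits(config, "consensus_config"))
  n <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("s%03d", seq_len(n))
  if (n < config$k) stop("need at least k samples (n = ", n, ", k = ",
                         config$k, ")")
  ord <- order(colnames(x))               # canonical sample order
  xs <- x[, ord, drop = FALSE]
  m <- ceiling(config$pItem * n)

  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  set.seed(config$seed)
  for (rep_i in seq_len(config$repetitions)) {
    idx <- sort(sample.int(n, m))
    d <- sample_distance(xs[, idx, drop = FALSE], config$inner_distance)
    cl <- stats::cutree(stats::hclust(d, method = config$inner_linkage),
                        k = min(config$k, m))
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    for (g in unique(cl)) {
      members <- idx[cl == g]
      co_cluster[members, members] <- co_cluster[members, members] + 1
    }
  }
  consensus <- ifelse(co_sample > 0, co_cluster / pmax(co_sample, 1), 0.5)
  diag(consensus) <- 1
  dimnames(consensus) <- list(colnames(xs), colnames(xs))
  dimnames(co_sample) <- dimnames(consensus)

  outer_d <- stats::as.dist(1 - consensus)
  labels_sorted <- stats::cutree(
    stats::hclust(outer_d, method = config$outer_linkage), k = config$k)
  labels <- integer(n)
  labels[ord] <- labels_sorted
  names(labels) <- colnames(x)

  structure(list(consensus_matrix = consensus, co_sample_counts = co_sample,
                 labels = labels, config = config),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d samples, k = %d, %d repetitions\n",
              length(x$labels), x$config$k, x$config$repetitions))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Per-sample ICR score
#'
#' The arithmetic mean of the 20 panel genes' log2 values; the axis of the
#' ICR1 -> ICR4 immune continuum. All 20 genes must be present - the
#' classifier panel is never silently imputed.
#'
#' @param ds an [expression_dataset()].
#' @return Named numeric vector, one score per sample.
#' @export
icr_score <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  check_present(ds$gene_ids, icr_panel(), "ICR panel gene(s)")
  colMeans(ds$values[icr_panel(), , drop = FALSE])
}

#' Rename clusters ICR1..ICRk by ascending mean ICR score
#'
#' Clusters are relabeled so that class 1 has the lowest within-cluster mean
#' score and class k the highest (the immune-continuum ordering). Ties in
#' cluster means are broken by cluster size, then lowest original index,
#' with a message.
#'
#' @param result a [consensus_cluster()] result (or any integer label
#'   vector).
#' @param scores per-sample ICR scores aligned with the labels.
#' @return Integer vector of classes 1..k, same order and names as the
#'   input labels.
#' @export
assign_icr_labels <- function(result, scores) {
  labels <- if (inherits(result, "consensus_result")) result$labels else result
  if (length(labels) != length(scores)) {
    stop("labels and scores must be aligned")
  }
  cl_ids <- sort(unique(labels))
  mean_score <- vapply(cl_ids, function(g) mean(scores[labels == g]), 0)
  size <- vapply(cl_ids, function(g) sum(labels == g), 0L)
  if (anyDuplicated(mean_score)) {
    message("tie in cluster mean scores; broken by size then index")
  }
  o <- order(mean_score, size, cl_ids)
  new_label <- integer(max(cl_ids))
  new_label[cl_ids[o]] <- seq_along(cl_ids)
  out <- new_label[labels]
  names(out) <- names(labels)
  out
}

#' Collapse ICR classes to ICR1 vs ICR2-4
#'
#' @param icr_class integer vector with values in 1..4.
#' @return Factor with levels `"ICR1"`, `"ICR2-4"`. If only one level is
#'   present (degenerate cohort) a warning flags that downstream association
#'   is undefined.
#' @export
collapse_classes <- function(icr_class) {
  if (!all(icr_class %in% 1:4)) {
    stop("icr_class values must be in 1..4")
  }
  out <- factor(ifelse(icr_class == 1L, "ICR1", "ICR2-4"),
                levels = c("ICR1", "ICR2-4"))
  if (length(unique(out)) < 2L) {
    warning("single-level ICR collapse; association downstream is undefined")
  }
  out
}

#' Classify one cohort into ICR classes
#'
#' Convenience wrapper: extracts the 20-gene panel, runs
#' [consensus_cluster()], computes [icr_score()] and applies the
#' mean-score relabeling and the binary collapse.
#'
#' @param ds an [expression_dataset()] containing all 20 panel genes.
#' @param config a [consensus_config()].
#' @return List: `icr_class` (1-4), `icr_binary` (factor ICR1/ICR2-4),
#'   `score`, `consensus` (the [consensus_cluster()] result).
#' @export
classify_icr <- function(ds, config = consensus_config()) {
  stopifnot(inherits(ds, "expression_dataset"))
  check_present(ds$gene_ids, icr_panel(), "ICR panel gene(s)")
  panel_x <- ds$values[icr_panel(), , drop = FALSE]
  res <- consensus_cluster(panel_x, config)
  sc <- icr_score(ds)
  cls <- assign_icr_labels(res, sc)
  list(icr_class = cls,
       icr_binary = suppressWarnings(collapse_classes(cls)),
       score = sc, consensus = res)
}
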