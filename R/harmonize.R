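#' Quantile normalization of a log2 expression dataset
#'
#' Forces every sample (column) onto the identical empirical distribution:
#' the mean over samples of the per-rank sorted values. Within-sample gene
#' rank order is preserved. Tied values receive the mean of the quantile
#' values of their tied ranks.
#'
#' @param ds an [expression_dataset()] with at least 2 samples.
#' @return An [expression_dataset()] of the same shape.
#' @export
quantile_normalize <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  x <- ds$values
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    v <- numeric(length(col))
    v[order(col)] <- ref
    # tied input values share the mean of their assigned quantile values
    stats::ave(v, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(x)
  expression_dataset(out, cohort_id = ds$cohort_id)
}

#' Within-cohort z-score of one gene
#'
#' Standardizes a gene's log2 values to mean 0, SD 1 (n - 1 denominator)
#' using the cohort's own samples as the reference population. Used to make
#' PDL1 (CD274) expression comparable across cohorts before pooling.
#'
#' @param ds an [expression_dataset()].
#' @param gene gene symbol present in `ds`.
#' @return Named numeric vector of per-sample z-scores.
#' @export
standardize_gene <- function(ds, gene) {
  stopifnot(inherits(ds, "expression_dataset"))
  check_present(ds$gene_ids, gene, "gene")
  zscore(ds$values[gene, ], what = gene)
}

#' Pool per-cohort analysis results into one patient-level table
#'
#' Concatenates per-cohort clinical tables together with the per-cohort
#' class labels and binarized/standardized signature columns. Expression
#' values are never pooled across cohorts (classification, scoring and
#' binarization all run per cohort); only labels and scores travel.
#'
#' @param cohort_tables list of data.frames, one per cohort, sharing an
#'   identical column schema and each carrying `patient_id` and `cohort`.
#' @return A single data.frame with one row per patient.
#' @export
pool_datasets <- function(cohort_tables) {
  stopifnot(is.list(cohort_tables), length(cohort_tables) >= 1L)
  schema <- names(cohort_tables[[1]])
  for (i in seq_along(cohort_tables)) {
    missing <- setdiff(schema, names(cohort_tables[[i]]))
    extra <- setdiff(names(cohort_tables[[i]]), schema)
    if (length(missing) || length(extra)) {
      stop("cohort table ", i, " schema mismatch; missing: ",
           paste(missing, collapse = ", "), "; unexpected: ",
           paste(extra, collapse = ", "))
    }
  }
  pooled <- do.call(rbind, c(cohort_tables, list(make.row.names = FALSE)))
  if (anyDuplicated(pooled$patient_id)) {
    stop("duplicate patient IDs across cohorts: ",
         paste(unique(pooled$patient_id[duplicated(pooled$patient_id)]),
               collapse = ", "))
  }
  pooled
}

#' Collapse duplicate gene rows by symbol
#'
#' Multiple probes mapping to one symbol are averaged (mean per symbol).
#'
#' @param ds an [expression_dataset()]-like matrix with possibly duplicated
#'   row names, or a matrix.
#' @param cohort_id cohort label for the result when `ds` is a matrix.
#' @return An [expression_dataset()] with unique gene symbols.
#' @export
collapse_duplicate_genes <- function(ds, cohort_id = "cohort1") {
  m <- if (inherits(ds, "expression_dataset")) ds$values else ds
  if (inherits(ds, "expression_dataset")) cohort_id <- ds$cohort_id
  if (anyDuplicated(rownames(m))) {
    sym <- rownames(m)
    m <- rowsum(m, sym)
    m <- m / as.vector(table(sym)[rownames(m)])
  }
  expression_dataset(m, cohort_id = cohort_id)
}
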