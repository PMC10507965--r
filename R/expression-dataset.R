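#' Expression dataset container
#'
#' A light container for a genes x samples matrix of log2 expression values
#' together with its cohort identity. Gene symbols are row names, sample IDs
#' column names; both must be unique and all values finite.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are taken as gene symbols and sample IDs unless overridden.
#' @param gene_ids,sample_ids optional character vectors overriding dimnames.
#' @param cohort_id single string naming the cohort the samples belong to.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `cohort_id`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("CD8A", "GZMA", "PRF1"), c("s1", "s2")))
#' ds <- expression_dataset(m, cohort_id = "demo")
#' @export
expression_dataset <- function(values, gene_ids = rownames(values),
                               sample_ids = colnames(values),
                               cohort_id = "cohort1") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix (genes x samples)")
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required (dimnames or arguments)")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) stop("gene_ids length != nrow(values)")
  if (length(sample_ids) != ncol(values)) stop("sample_ids length != ncol(values)")
  if (anyDuplicated(gene_ids)) stop("duplicate gene symbols; collapse first")
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (!all(is.finite(values))) stop("expression values must be finite")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         cohort_id = as.character(cohort_id)[1]),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples, cohort '%s'\n",
              nrow(x$values), ncol(x$values), x$cohort_id))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Write / read an expression dataset as TSV
#'
#' Plain-text round trip: genes as rows, a leading `gene` column, one column
#' per sample. The cohort ID travels in a `# cohort:` comment on line 1.
#'
#' @param ds an [expression_dataset()].
#' @param path file path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an `expression_dataset`.
#' @export
write_expression_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cohort: ", ds$cohort_id), con)
  df <- data.frame(gene = ds$gene_ids, ds$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  cohort <- if (startsWith(first, "# cohort:")) {
    trimws(sub("^# cohort:", "", first))
  } else "cohort1"
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_dataset(m, cohort_id = cohort)
}

# Clinical table schema shared by the generator, pooling and association code.
clinical_columns <- function() {
  c("patient_id", "cohort", "age", "sex", "smoker", "histology",
    "mutation", "dcb", "dfs_months", "dfs_event")
}

#' Validate a clinical table
#'
#' Checks the per-patient covariate/outcome table against the documented
#' schema: `patient_id`, `cohort`, `age` (years), `sex` (male/female),
#' `smoker` (current/former/non), `histology` (squamous/non-squamous),
#' `mutation` (mutated/wild-type), `dcb` (0/1 durable clinical benefit),
#' `dfs_months`, `dfs_event` (0/1). Missing covariates are allowed (NA);
#' they are excluded listwise per model downstream.
#'
#' @param clin data.frame.
#' @return `clin`, invisibly, if valid; otherwise an error naming the
#'   first offending column.
#' @export
validate_clinical <- function(clin) {
  check_present(names(clin), clinical_columns(), "clinical table columns")
  if (anyDuplicated(clin$patient_id)) stop("duplicate patient_id in clinical table")
  chk_lev <- function(col, levels) {
    bad <- !is.na(clin[[col]]) & !(clin[[col]] %in% levels)
    if (any(bad)) stop("invalid values in clinical column '", col, "': ",
                       paste(unique(clin[[col]][bad]), collapse = ", "))
  }
  chk_lev("sex", c("male", "female"))
  chk_lev("smoker", c("current", "former", "non"))
  chk_lev("histology", c("squamous", "non-squamous"))
  chk_lev("mutation", c("mutated", "wild-type"))
  chk_lev("dcb", c(0, 1))
  chk_lev("dfs_event", c(0, 1))
  if (any(!is.na(clin$dfs_months) & clin$dfs_months < 0)) {
    stop("dfs_months must be >= 0")
  }
  invisible(clin)
}
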