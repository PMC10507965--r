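#' Raw probe-count container
#'
#' Holds a probes x samples matrix of non-negative integer counts plus the
#' probe-class annotation used by nCounter-style processing: `endogenous`
#' probes are the targets; `negative` controls estimate background;
#' `positive` controls and `housekeeping` probes are the normalization
#' reference.
#'
#' @param counts non-negative numeric matrix, probes x samples, with probe
#'   IDs as row names and sample IDs as column names.
#' @param probe_class character vector, one of
#'   `c("endogenous", "negative", "positive", "housekeeping")` per probe.
#' @param gene_symbol character vector of gene symbols (endogenous probes);
#'   defaults to the probe IDs.
#' @return An object of class `raw_counts`.
#' @export
raw_counts <- function(counts, probe_class, gene_symbol = rownames(counts)) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (probes x samples)")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  probe_class <- as.character(probe_class)
  if (length(probe_class) != nrow(counts)) {
    stop("probe_class must have one entry per probe")
  }
  ok <- c("endogenous", "negative", "positive", "housekeeping")
  bad <- setdiff(unique(probe_class), ok)
  if (length(bad)) stop("unknown probe classes: ", paste(bad, collapse = ", "))
  if (!any(probe_class == "negative")) {
    stop("at least one negative-control probe is required")
  }
  if (!any(probe_class %in% c("positive", "housekeeping"))) {
    stop("at least one reference (positive or housekeeping) probe is required")
  }
  structure(list(counts = counts, probe_class = probe_class,
                 gene_symbol = as.character(gene_symbol)),
            class = "raw_counts")
}

#' @export
print.raw_counts <- function(x, ...) {
  cat(sprintf("<raw_counts> %d probes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%d %s", table(x$probe_class),
                            names(table(x$probe_class))), collapse = ", ")))
  invisible(x)
}

#' Background subtraction by negative-control geometric mean
#'
#' Per sample, the background is the geometric mean of the negative-control
#' counts; it is subtracted from every endogenous count, flooring at
#' `floor`. Control probes pass through unmodified so downstream reference
#' normalization still sees them. Zero negative counts are handled by
#' computing the geometric mean on counts + 1 and subtracting 1, which
#' avoids a single zero collapsing the background to 0.
#'
#' @param raw a [raw_counts()] object.
#' @param floor minimum post-subtraction endogenous count (default 1, so
#'   log2 stays defined downstream; 0 also supported).
#' @return A `raw_counts` object with attribute `background` (per-sample
#'   estimate).
#' @export
subtract_background <- function(raw, floor = 1) {
  stopifnot(inherits(raw, "raw_counts"), floor >= 0)
  neg <- raw$counts[raw$probe_class == "negative", , drop = FALSE]
  bg <- apply(neg, 2, function(x) {
    if (any(x == 0)) geomean(x + 1) - 1 else geomean(x)
  })
  endo <- raw$probe_class == "endogenous"
  out <- raw$counts
  out[endo, ] <- pmax(sweep(out[endo, , drop = FALSE], 2, bg, `-`), floor)
  res <- raw_counts(out, raw$probe_class, raw$gene_symbol)
  attr(res, "background") <- bg
  res
}

#' Reference-probe geometric-mean normalization
#'
#' Per sample i, computes the geometric mean g_i of the reference probes
#' (housekeeping + positive controls), then rescales every count in that
#' sample by f_i = ref / g_i where ref is by default the arithmetic mean of
#' the g_i over samples (nSolver convention) or a fixed value.
#'
#' @param raw a [raw_counts()] object (background already subtracted).
#' @param reference `"mean"` (default) or a fixed positive number.
#' @return A `raw_counts` object with attribute `scale_factors`.
#' @export
normalize_geomean <- function(raw, reference = "mean") {
  stopifnot(inherits(raw, "raw_counts"))
  ref_rows <- raw$probe_class %in% c("positive", "housekeeping")
  g <- apply(raw$counts[ref_rows, , drop = FALSE], 2, function(x) {
    if (any(x <= 0)) 0 else geomean(x)
  })
  if (any(g == 0)) {
    stop("degenerate reference probes (geometric mean 0) in sample(s): ",
         paste(colnames(raw$counts)[g == 0], collapse = ", "))
  }
  target <- if (identical(reference, "mean")) mean(g) else {
    stopifnot(is.numeric(reference), reference > 0)
    reference
  }
  f <- target / g
  out <- sweep(raw$counts, 2, f, `*`)
  res <- raw_counts(out, raw$probe_class, raw$gene_symbol)
  attr(res, "scale_factors") <- f
  res
}

#' Log2 transform of normalized counts
#'
#' Maps endogenous probe counts to `log2(count + offset)` and returns an
#' [expression_dataset()] keyed by gene symbol (duplicate symbols collapsed
#' by mean).
#'
#' @param raw a normalized [raw_counts()] object.
#' @param offset additive offset before log2 (default 1).
#' @param cohort_id cohort label for the resulting dataset.
#' @return An [expression_dataset()].
#' @export
to_log2 <- function(raw, offset = 1, cohort_id = "cohort1") {
  stopifnot(inherits(raw, "raw_counts"), offset >= 0)
  endo <- raw$probe_class == "endogenous"
  m <- log2(raw$counts[endo, , drop = FALSE] + offset)
  sym <- raw$gene_symbol[endo]
  if (anyDuplicated(sym)) {
    m <- rowsum(m, sym)                      # rows sorted by symbol
    m <- m / as.vector(table(sym)[rownames(m)])
  } else {
    rownames(m) <- sym
  }
  expression_dataset(m, cohort_id = cohort_id)
}

#' Run the full nCounter-style normalization chain
#'
#' [subtract_background()], then [normalize_geomean()], then [to_log2()].
#'
#' @inheritParams subtract_background
#' @inheritParams normalize_geomean
#' @inheritParams to_log2
#' @return An [expression_dataset()].
#' @export
nanostring_normalize <- function(raw, floor = 1, reference = "mean",
                                 offset = 1, cohort_id = "cohort1") {
  to_log2(normalize_geomean(subtract_background(raw, floor), reference),
          offset, cohort_id)
}

#' Read raw probe counts from a CSV dialect of RCC content
#'
#' Expected columns: `probe_id`, `probe_class`, `gene_symbol`, then one
#' numeric count column per sample.
#'
#' @param path CSV path.
#' @return A [raw_counts()] object.
#' @export
read_raw_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_present(names(df), c("probe_id", "probe_class", "gene_symbol"),
                "raw count CSV columns")
  m <- as.matrix(df[, setdiff(names(df),
                              c("probe_id", "probe_class", "gene_symbol")),
                    drop = FALSE])
  rownames(m) <- df$probe_id
  raw_counts(m, df$probe_class, df$gene_symbol)
}

#' @rdname read_raw_counts_csv
#' @param raw a [raw_counts()] object to write.
#' @export
write_raw_counts_csv <- function(raw, path) {
  stopifnot(inherits(raw, "raw_counts"))
  df <- data.frame(probe_id = rownames(raw$counts),
                   probe_class = raw$probe_class,
                   gene_symbol = raw$gene_symbol,
                   raw$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
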