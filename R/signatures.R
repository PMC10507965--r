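#' Gene set with optional direction weights
#'
#' @param name set name.
#' @param genes character vector of member symbols; forced uppercase;
#'   duplicates are rejected.
#' @param weights optional named numeric direction weights (+1/-1 or
#'   continuous), aligned with `genes`.
#' @return List of class `gene_set`.
#' @export
gene_set <- function(name, genes, weights = NULL) {
  genes <- toupper(as.character(genes))
  if (!length(genes)) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) {
    stop("gene set '", name, "' has duplicate symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (!is.null(weights)) {
    if (length(weights) != length(genes)) {
      stop("weights must align with genes")
    }
    weights <- as.numeric(weights)
    names(weights) <- genes
  }
  structure(list(name = name, genes = genes, weights = weights),
            class = "gene_set")
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member symbols.
#'
#' @param path GMT file path.
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    gene_set(f[1], f[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Metagene score of a gene set
#'
#' Mean of the member genes' log2 values per sample (weighted mean when the
#' set carries direction weights). Members absent from the dataset are
#' dropped; the missing fraction is reported as an attribute. If no member
#' is present the score is all-NA rather than an error, so a panel of many
#' sets degrades gracefully.
#'
#' @param ds an [expression_dataset()].
#' @param gs a [gene_set()].
#' @return Named numeric vector (per sample) with attribute
#'   `missing_fraction`.
#' @export
metagene_score <- function(ds, gs) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(gs, "gene_set"))
  present <- intersect(gs$genes, ds$gene_ids)
  miss_frac <- 1 - length(present) / length(gs$genes)
  if (!length(present)) {
    out <- rep(NA_real_, length(ds$sample_ids))
    names(out) <- ds$sample_ids
    attr(out, "missing_fraction") <- 1
    return(out)
  }
  m <- ds$values[present, , drop = FALSE]
  out <- if (is.null(gs$weights)) {
    colMeans(m)
  } else {
    w <- gs$weights[present]
    colSums(m * w) / sum(abs(w))
  }
  attr(out, "missing_fraction") <- miss_frac
  out
}

#' Cytolytic activity score
#'
#' Arithmetic mean of log2(GZMA) and log2(PRF1) per sample - the log2 of
#' the geometric mean of the two effector transcripts on the linear scale.
#'
#' @param ds an [expression_dataset()] containing GZMA and PRF1.
#' @return Named numeric vector per sample.
#' @export
cytolytic_score <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  check_present(ds$gene_ids, c("GZMA", "PRF1"), "cytolytic score gene(s)")
  colMeans(ds$values[c("GZMA", "PRF1"), , drop = FALSE])
}

#' Binarize a score at the first quintile
#'
#' Within each cohort, samples at or below the 20th percentile of the score
#' are labeled `"low"`, the rest `"high"`. Ties at the cut all go "low"
#' (the `<=` convention). An all-equal score cannot be split and is
#' refused.
#'
#' @param scores numeric vector.
#' @param cohort optional cohort labels (same length); the quintile is
#'   computed within each cohort. Default: one cohort.
#' @return Factor with levels `"low"`, `"high"`.
#' @export
quintile_binarize <- function(scores, cohort = NULL) {
  if (is.null(cohort)) cohort <- rep("all", length(scores))
  if (length(cohort) != length(scores)) stop("cohort must align with scores")
  out <- character(length(scores))
  for (g in unique(cohort)) {
    idx <- cohort == g
    s <- scores[idx]
    if (sum(idx) < 5L) stop("cohort '", g, "' has < 5 samples; quintile cut undefined")
    if (length(unique(s)) == 1L) {
      stop("degenerate scores (all equal) in cohort '", g,
           "'; binarization refused")
    }
    cut <- stats::quantile(s, 0.2, names = FALSE)
    out[idx] <- ifelse(s <= cut, "low", "high")
  }
  factor(out, levels = c("low", "high"))
}

#' Score the full signature panel for one cohort
#'
#' Computes, per sample: the ICR score, every metagene in the signature
#' database, the cytolytic activity score, standardized PDL1 (CD274)
#' expression, and the Th1/Th2 ratio (Th1 metagene minus Th2 metagene,
#' log2 domain). Unknown requested signatures are skipped with a warning.
#'
#' @param ds an [expression_dataset()].
#' @param signature_db named list of [gene_set()]s (see [read_gmt()]) or a
#'   GMT path; default the shipped database.
#' @return data.frame, one row per sample, first columns `sample_id` and
#'   `cohort`; attribute `missing_fractions` records per-set missingness.
#' @export
score_panel <- function(ds, signature_db = default_signature_db()) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.character(signature_db)) signature_db <- read_gmt(signature_db)
  out <- data.frame(sample_id = ds$sample_ids, cohort = ds$cohort_id,
                    icr_score = icr_score(ds), stringsAsFactors = FALSE)
  miss <- numeric(0)
  for (gs in signature_db) {
    sc <- metagene_score(ds, gs)
    miss[gs$name] <- attr(sc, "missing_fraction")
    if (all(is.na(sc))) {
      warning("signature '", gs$name, "' has no member genes present; skipped")
      next
    }
    out[[gs$name]] <- as.numeric(sc)
  }
  if (all(c("GZMA", "PRF1") %in% ds$gene_ids)) {
    out$cytolytic <- as.numeric(cytolytic_score(ds))
  }
  if ("CD274" %in% ds$gene_ids) {
    out$PDL1_z <- as.numeric(standardize_gene(ds, "CD274"))
  }
  if (all(c("BINDEA_TH1", "BINDEA_TH2") %in% names(out))) {
    out$th1_th2_ratio <- out$BINDEA_TH1 - out$BINDEA_TH2
  }
  attr(out, "missing_fractions") <- miss
  rownames(out) <- NULL
  out
}

#' Binarize the comparator predictors of a score table
#'
#' Adds `"low"`/`"high"` factors for TIS, TLS and standardized PDL1 at the
#' within-cohort first quintile, the form in which they enter the DCB
#' models.
#'
#' @param scores a [score_panel()] table (may span several cohorts).
#' @param predictors columns to binarize; defaults to the three comparator
#'   predictors.
#' @return `scores` with `<predictor>_class` factor columns appended.
#' @export
binarize_predictors <- function(scores,
                                predictors = c("TIS", "TLS", "PDL1_z")) {
  present <- intersect(predictors, names(scores))
  skipped <- setdiff(predictors, present)
  if (length(skipped)) {
    warning("predictor(s) not in score table, skipped: ",
            paste(skipped, collapse = ", "))
  }
  for (p in present) {
    scores[[paste0(p, "_class")]] <-
      quintile_binarize(scores[[p]], scores$cohort)
  }
  scores
}
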