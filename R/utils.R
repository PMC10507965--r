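#' Geometric mean
#'
#' @param x numeric vector, all values > 0.
#' @return The geometric mean `exp(mean(log(x)))`.
#' @keywords internal
geomean <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples.
#' Used to quantify recovery of planted classes by the consensus classifier.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return Numeric scalar; 1 for identical partitions (up to relabeling),
#'   about 0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# Column z-score with n-1 denominator; errors on zero variance.
zscore <- function(x, what = "values") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zero variance, cannot standardize: ", what)
  }
  (x - mean(x)) / s
}

# stop() unless all names in `need` are present, naming the absentees
check_present <- function(have, need, label) {
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop(label, " missing: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
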