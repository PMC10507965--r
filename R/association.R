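#' Outcome-by-group contingency table
#'
#' Counts successes and failures of a boolean outcome per group level.
#' Empty groups are retained as zero rows and flagged.
#'
#' @param group factor or vector of group labels.
#' @param outcome logical/0-1 outcome, aligned with `group`, non-missing.
#' @return A list of class `contingency`: `counts` (k x 2 matrix, columns
#'   `yes`/`no`), `rates` (per-group outcome rate), `n`.
#' @export
contingency_table <- function(group, outcome) {
  if (length(group) != length(outcome)) stop("group and outcome must align")
  if (any(is.na(group)) || any(is.na(outcome))) {
    stop("group and outcome must be non-missing")
  }
  outcome <- as.integer(as.logical(outcome))
  group <- if (is.factor(group)) group else factor(group)
  yes <- tapply(outcome, group, sum, default = 0L)
  tot <- tapply(outcome, group, length, default = 0L)
  counts <- cbind(yes = as.integer(yes), no = as.integer(tot - yes))
  rownames(counts) <- levels(group)
  if (any(tot == 0)) {
    warning("empty group(s): ",
            paste(levels(group)[tot == 0], collapse = ", "))
  }
  rates <- as.numeric(ifelse(tot > 0, yes / tot, NaN))
  names(rates) <- levels(group)
  structure(list(counts = counts, rates = rates, n = sum(counts)),
            class = "contingency")
}

#' Odds ratio with Wald 95% confidence interval
#'
#' For a 2x2 table `[[a, b], [c, d]]` (rows = groups, columns = yes/no),
#' OR = (a d)/(b c) and the CI is `exp(log OR +/- z sqrt(1/a+1/b+1/c+1/d))`.
#' A zero cell triggers the Haldane-Anscombe +0.5 correction on all cells,
#' flagged in the result; a fully zero row or column leaves the OR
#' undefined and errors.
#'
#' @param tab 2x2 numeric matrix of counts, or a 2-level [contingency_table()].
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with `or`, `ci_low`, `ci_high`, `p` (Wald),
#'   `corrected`, `n`.
#' @export
odds_ratio_wald <- function(tab, conf_level = 0.95) {
  if (inherits(tab, "contingency")) tab <- tab$counts
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stop("odds ratio needs a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("odds ratio undefined: a whole row or column is zero")
  }
  n <- sum(tab)
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(or = exp(log_or),
             ci_low = exp(log_or - z * se),
             ci_high = exp(log_or + z * se),
             p = 2 * stats::pnorm(-abs(log_or / se)),
             corrected = corrected, n = n)
}

# log multivariate-hypergeometric probability of first-row counts `a`
# given column margins `cols` and first-row margin r1
log_table_prob <- function(a, cols, r1, n) {
  sum(lchoose(cols, a)) - lchoose(n, r1)
}

#' Fisher's exact test for 2 x k tables
#'
#' Exact two-sided p-value by full enumeration of all tables with the
#' observed margins, summing the (multivariate-hypergeometric)
#' probabilities of every table whose probability does not exceed that of
#' the observed table (probability-mass ordering). Feasible for the table
#' sizes arising here (~1e4-1e5 candidate tables).
#'
#' @param tab 2 x k matrix of non-negative integer counts (or k x 2,
#'   transposed automatically; or a [contingency_table()]).
#' @return List: `p`, `n_tables` enumerated, `flagged` (TRUE when a margin
#'   is zero and p = 1 by convention).
#' @export
fisher_exact <- function(tab) {
  if (inherits(tab, "contingency")) tab <- t(tab$counts)
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L && ncol(tab) == 2L) tab <- t(tab)
  if (nrow(tab) != 2L) stop("fisher_exact needs a 2 x k table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  k <- ncol(tab)
  cols <- colSums(tab)
  r1 <- sum(tab[1, ])
  n <- sum(tab)
  if (k < 2L || r1 == 0 || r1 == n || any(cols == 0)) {
    return(list(p = 1, n_tables = 0L, flagged = TRUE))
  }
  obs <- log_table_prob(tab[1, ], cols, r1, n)

  # enumerate first-row vectors a_1..a_k with sum r1, 0 <= a_j <= cols_j
  p_total <- 0
  n_tables <- 0L
  a <- integer(k)
  recurse <- function(j, remaining, acc) {
    if (j == k) {
      if (remaining <= cols[k]) {
        lp <- acc + lchoose(cols[k], remaining) - lchoose(n, r1)
        n_tables <<- n_tables + 1L
        if (lp <= obs + 1e-7) p_total <<- p_total + exp(lp)
      }
      return(invisible())
    }
    lo <- max(0L, remaining - sum(cols[(j + 1):k]))
    hi <- min(cols[j], remaining)
    if (lo > hi) return(invisible())
    for (aj in lo:hi) {
      recurse(j + 1L, remaining - aj, acc + lchoose(cols[j], aj))
    }
  }
  recurse(1L, r1, 0)
  list(p = min(1, p_total), n_tables = n_tables, flagged = FALSE)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood binomial-logit fit. Starts from zero slopes with the
#' intercept at the logit of the mean outcome; converges when the maximum
#' absolute score (gradient) falls below `tol` or after `max_iter`
#' iterations. Wald standard errors come from the inverse observed
#' information; odds ratios are the exponentiated coefficients. Separation
#' (a diverging coefficient) is reported via `converged`/`separation`
#' flags, never silently.
#'
#' @param design data.frame of covariates (factors expanded by
#'   `model.matrix(~ .)`) or a numeric design matrix WITHOUT intercept.
#' @param outcome 0/1 or logical response.
#' @param conf_level Wald CI level (default 0.95).
#' @param tol,max_iter convergence controls.
#' @return List of class `logistic_fit`: `coefficients` tidy data.frame
#'   (term, estimate, se, or, ci_low, ci_high, p), `converged`,
#'   `separation`, `loglik`, `n`.
#' @export
logistic_fit <- function(design, outcome, conf_level = 0.95,
                         tol = 1e-8, max_iter = 25L) {
  y <- as.integer(as.logical(outcome))
  if (is.data.frame(design)) {
    cc <- if (ncol(design)) stats::complete.cases(design) & !is.na(y) else !is.na(y)
    design <- design[cc, , drop = FALSE]
    y <- y[cc]
    X <- if (ncol(design)) {
      stats::model.matrix(~ ., data = design)
    } else {
      matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
    }
  } else {
    X <- cbind(`(Intercept)` = 1, as.matrix(design))
  }
  n <- length(y)
  if (length(unique(y)) < 2L) stop("outcome must have both levels")
  if (n <= ncol(X)) stop("need more observations than parameters")

  beta <- numeric(ncol(X))
  beta[1] <- stats::qlogis(mean(y))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    XtWX <- crossprod(X, X * w)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(X, X * w)
  vcov_ok <- tryCatch({vc <- solve(info); TRUE}, error = function(e) FALSE)
  se <- if (vcov_ok) sqrt(diag(vc)) else rep(NA_real_, length(beta))
  separation <- any(abs(beta[-1]) > 15) || any(!is.finite(se))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(
    term = colnames(X), estimate = beta, se = se,
    or = exp(beta), ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL
  loglik <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  structure(list(coefficients = coefs, converged = converged,
                 separation = separation, loglik = loglik, n = n),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, converged = %s%s\n", x$n,
              x$converged, if (x$separation) " [SEPARATION]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition; used for class-wise comparisons
#' of continuous signature scores.
#'
#' @param values numeric vector.
#' @param groups group labels aligned with `values` (>= 2 groups).
#' @return List: `f`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  k <- nlevels(droplevels(groups))
  n <- length(values)
  if (k < 2L) stop("ANOVA needs >= 2 groups")
  if (n <= k) stop("ANOVA needs more observations than groups")
  grand <- mean(values)
  mg <- tapply(values, groups, mean)
  ng <- tapply(values, groups, length)
  ss_between <- sum(ng * (mg - grand)^2)
  ss_within <- sum((values - mg[groups])^2)
  df_b <- k - 1L
  df_w <- n - k
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w)
}

#' Cochran's Q homogeneity test across cohort 2x2 tables
#'
#' Fixed-effects meta-analytic homogeneity of per-cohort log odds ratios:
#' Q = sum w_i (theta_i - theta_hat)^2 with inverse-variance weights and
#' theta_hat the weighted mean; p from chi-square with (#cohorts - 1) df.
#' Tables with a zero cell receive the +0.5 Haldane-Anscombe correction.
#'
#' @param tables list of 2x2 count matrices, one per cohort (>= 2 with
#'   estimable log-ORs, i.e. no all-zero row/column after correction).
#' @return List: `q`, `df`, `p`, `log_or` (per cohort), `pooled_log_or`.
#' @export
homogeneity_test <- function(tables) {
  stopifnot(is.list(tables))
  est <- lapply(tables, function(tab) {
    tab <- as.matrix(tab)
    if (!identical(dim(tab), c(2L, 2L))) stop("each table must be 2x2")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
    if (any(tab == 0)) tab <- tab + 0.5
    list(lo = log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])),
         v = sum(1 / tab))
  })
  est <- est[!vapply(est, is.null, TRUE)]
  if (length(est) < 2L) stop("need >= 2 cohorts with estimable odds ratios")
  lo <- vapply(est, `[[`, 0, "lo")
  w <- 1 / vapply(est, `[[`, 0, "v")
  pooled <- sum(w * lo) / sum(w)
  q <- sum(w * (lo - pooled)^2)
  df <- length(est) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE),
       log_or = lo, pooled_log_or = pooled)
}
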