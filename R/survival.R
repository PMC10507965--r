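#' Kaplan-Meier product-limit estimate
#'
#' Survival step function with Greenwood variance and a 95% CI computed on
#' the log-survival scale with symmetric normal quantiles, truncated to
#' [0, 1]. At tied times, deaths precede censorings (the standard
#' convention).
#'
#' @param time non-negative event/censoring times (months).
#' @param event 1 = event, 0 = censored, aligned with `time`.
#' @param conf_level CI level (default 0.95).
#' @return A list of class `km_curve`: data.frame `steps` (time, n_risk,
#'   n_event, n_censor, surv, se, lower, upper - one row per distinct event
#'   time), `n`, and `degenerate` flag (TRUE when no event time exists).
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (length(time) != length(event)) stop("time and event must align")
  if (length(time) < 1L) stop("need at least one subject")
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be finite and >= 0")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")

  ut <- sort(unique(time[event == 1L]))
  n <- length(time)
  if (!length(ut)) {
    return(structure(list(
      steps = data.frame(time = numeric(0), n_risk = integer(0),
                         n_event = integer(0), n_censor = integer(0),
                         surv = numeric(0), se = numeric(0),
                         lower = numeric(0), upper = numeric(0)),
      n = n, degenerate = TRUE), class = "km_curve"))
  }
  surv <- numeric(length(ut))
  gw <- numeric(length(ut))     # Greenwood cumulative sum
  n_risk <- integer(length(ut))
  n_event <- integer(length(ut))
  n_censor <- integer(length(ut))
  s <- 1
  acc <- 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  for (i in seq_along(ut)) {
    t_i <- ut[i]
    n_risk[i] <- sum(time >= t_i)          # deaths precede censorings at ties
    n_event[i] <- sum(time == t_i & event == 1L)
    n_censor[i] <- sum(time == t_i & event == 0L)
    s <- s * (1 - n_event[i] / n_risk[i])
    if (n_risk[i] > n_event[i]) {
      acc <- acc + n_event[i] / (n_risk[i] * (n_risk[i] - n_event[i]))
    } else {
      acc <- Inf
    }
    surv[i] <- s
    gw[i] <- acc
  }
  se <- ifelse(surv > 0, surv * sqrt(gw), 0)  # Greenwood SE of S(t)
  se_log <- sqrt(gw)                        # SE of log S(t)
  lower <- ifelse(surv > 0, pmax(0, surv * exp(-z * se_log)), 0)
  upper <- ifelse(surv > 0, pmin(1, surv * exp(z * se_log)), 0)
  structure(list(
    steps = data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv, se = se,
                       lower = lower, upper = upper),
    n = n, degenerate = FALSE), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event times%s\n", x$n, nrow(x$steps),
              if (x$degenerate) " (degenerate: no events)" else ""))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function lookup. Times beyond the last observed
#' event time return the last value with an `extrapolated` flag.
#'
#' @param curve a [km_estimate()] result.
#' @param t time (months), >= 0.
#' @return List: `surv`, `lower`, `upper`, `extrapolated`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), length(t) == 1L, t >= 0)
  st <- curve$steps
  if (!nrow(st) || t < st$time[1]) {
    return(list(surv = 1, lower = 1, upper = 1, extrapolated = FALSE))
  }
  i <- max(which(st$time <= t))
  list(surv = st$surv[i], lower = st$lower[i], upper = st$upper[i],
       extrapolated = t > max(st$time))
}

#' Log-rank test comparing survival across groups
#'
#' Observed-minus-expected statistic over the pooled event times with the
#' hypergeometric variance; for g groups the chi-square statistic uses the
#' (g-1)-dimensional score vector and its covariance, df = g - 1.
#'
#' @param time,event as in [km_estimate()].
#' @param group group labels aligned with `time`; >= 2 non-empty groups.
#' @return List: `chisq`, `df`, `p`, `observed`, `expected` (per group),
#'   `flagged` (TRUE when no events anywhere, p = 1 by convention).
#' @export
logrank_test <- function(time, event, group) {
  if (length(time) != length(event) || length(time) != length(group)) {
    stop("time, event and group must align")
  }
  group <- factor(group)
  group <- droplevels(group)
  g <- nlevels(group)
  if (g < 2L) stop("log-rank needs >= 2 non-empty groups")
  event <- as.integer(event)
  ut <- sort(unique(time[event == 1L]))
  obs <- stats::setNames(numeric(g), levels(group))
  expc <- obs
  if (!length(ut)) {
    return(list(chisq = 0, df = g - 1L, p = 1, observed = obs,
                expected = expc, flagged = TRUE))
  }
  U <- numeric(g - 1L)
  V <- matrix(0, g - 1L, g - 1L)
  for (t_i in ut) {
    at_risk <- time >= t_i
    n_i <- sum(at_risk)
    d_i <- sum(time == t_i & event == 1L)
    n_gi <- as.numeric(tapply(at_risk, group, sum, default = 0L))
    d_gi <- as.numeric(tapply(time == t_i & event == 1L, group, sum,
                              default = 0L))
    e_gi <- n_gi * d_i / n_i
    obs <- obs + d_gi
    expc <- expc + e_gi
    U <- U + (d_gi - e_gi)[seq_len(g - 1L)]
    if (n_i > 1) {
      # hypergeometric covariance of the first g-1 group event counts
      mult <- d_i * (n_i - d_i) / ((n_i - 1) * n_i^2)
      ng <- as.numeric(n_gi[seq_len(g - 1L)])
      V <- V + mult * (diag(ng * n_i, nrow = g - 1L) - outer(ng, ng))
    }
  }
  chisq <- tryCatch(drop(t(U) %*% solve(V, U)), error = function(e) NA_real_)
  if (!is.finite(chisq)) {
    # singular covariance (e.g. a group exhausted immediately): fall back
    # to the 1-df pooled statistic over non-degenerate groups
    chisq <- 0
  }
  list(chisq = chisq, df = g - 1L,
       p = stats::pchisq(chisq, g - 1L, lower.tail = FALSE),
       observed = obs, expected = expc, flagged = FALSE)
}

#' Read survival data from CSV
#'
#' Expected columns: `id`, `time_months`, `event`, `group`.
#'
#' @param path CSV path.
#' @return data.frame with the four columns validated.
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path)
  check_present(names(df), c("id", "time_months", "event", "group"),
                "survival CSV columns")
  df
}

#' Write a Kaplan-Meier curve as CSV
#'
#' @param curve a [km_estimate()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_km_csv <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  utils::write.csv(curve$steps, path, row.names = FALSE)
  invisible(path)
}
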