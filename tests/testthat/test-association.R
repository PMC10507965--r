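test_that("contingency_table counts and flags correctly", {
  ct <- contingency_table(rep(c("ICR1", "ICR2-4"), c(35, 127)),
                          c(rep(1, 3), rep(0, 32), rep(1, 44), rep(0, 83)))
  expect_equal(unname(ct$counts), matrix(c(3, 44, 32, 83), 2))
  expect_equal(unname(ct$rates), c(3 / 35, 44 / 127))
  expect_equal(ct$n, 162)
  # all-false outcomes put everything in the "no" column
  ct0 <- contingency_table(c("a", "a", "b"), c(0, 0, 0))
  expect_equal(unname(ct0$counts[, "yes"]), c(0L, 0L))
  # empty group flagged
  expect_warning(contingency_table(factor(c("a", "a"), c("a", "b")),
                                   c(1, 0)), "empty")
})

test_that("odds_ratio_wald reproduces the published 2x2 results", {
  pooled <- matrix(c(44, 83, 3, 32), 2, byrow = TRUE)  # ICR2-4 then ICR1
  r <- odds_ratio_wald(pooled)
  expect_equal(round(r$or, 2), 5.65)
  expect_equal(round(r$ci_low, 2), 1.64)
  expect_equal(round(r$ci_high, 2), 19.51)
  own <- matrix(c(10, 25, 1, 8), 2, byrow = TRUE)
  r2 <- odds_ratio_wald(own)
  expect_equal(round(r2$or, 2), 3.20)
  expect_equal(round(r2$ci_low, 2), 0.35)
  expect_equal(round(r2$ci_high, 2), 29.01)
  # symmetry
  expect_equal(odds_ratio_wald(matrix(5, 2, 2))$or, 1)
  # zero cell -> Haldane-Anscombe flagged
  rz <- odds_ratio_wald(matrix(c(0, 10, 5, 5), 2, byrow = TRUE))
  expect_true(rz$corrected)
  expect_true(rz$ci_low < rz$or & rz$or < rz$ci_high)
  expect_error(odds_ratio_wald(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "undefined")
})

test_that("fisher_exact matches the closed-form hypergeometric oracle", {
  tabs <- list(c(3, 32, 44, 83), c(1, 8, 10, 25), c(2, 0, 3, 7),
               c(5, 5, 5, 5), c(0, 12, 9, 1))
  for (v in tabs) {
    tab <- matrix(v, 2, byrow = TRUE)
    expect_equal(fisher_exact(tab)$p,
                 hyper_fisher_2x2(v[1], v[2], v[3], v[4]),
                 tolerance = 1e-10, label = paste(v, collapse = ","))
  }
  # and against R's implementation on a 2x4 table
  m <- rbind(c(3, 17, 13, 14), c(32, 31, 23, 29))
  expect_equal(fisher_exact(m)$p, fisher.test(m)$p.value, tolerance = 1e-7)
})

test_that("fisher_exact degenerate margins return p = 1, flagged", {
  r <- fisher_exact(matrix(c(0, 0, 3, 7), 2, byrow = TRUE))
  expect_equal(r$p, 1)
  expect_true(r$flagged)
  r2 <- fisher_exact(matrix(c(2, 3, 0, 0), 2))  # zero column margin
  expect_true(r2$flagged)
})

test_that("logistic_fit agrees with the saturated 2x2 identity and glm", {
  # single binary predictor reproduces odds_ratio_wald to 6 significant digits
  x <- c(rep(1, 127), rep(0, 35))
  y <- c(rep(1, 44), rep(0, 83), rep(1, 3), rep(0, 32))
  fit <- logistic_fit(matrix(x), y)
  wald <- odds_ratio_wald(matrix(c(44, 83, 3, 32), 2, byrow = TRUE))
  expect_equal(fit$coefficients$or[2], wald$or, tolerance = 1e-6)
  expect_equal(fit$coefficients$ci_low[2], wald$ci_low, tolerance = 1e-6)
  expect_equal(fit$coefficients$ci_high[2], wald$ci_high, tolerance = 1e-6)
  expect_true(fit$converged)
  # multivariate fit vs glm oracle
  set.seed(90)
  df <- data.frame(a = rnorm(200), b = factor(sample(c("x", "y"), 200, TRUE)))
  yy <- rbinom(200, 1, plogis(-0.5 + 0.8 * df$a + 0.6 * (df$b == "y")))
  ours <- logistic_fit(df, yy)
  theirs <- glm(yy ~ a + b, family = binomial(), data = df)
  expect_equal(ours$coefficients$estimate, unname(coef(theirs)),
               tolerance = 1e-6)
  expect_equal(ours$coefficients$se,
               unname(sqrt(diag(vcov(theirs)))), tolerance = 1e-6)
  # intercept-only model returns the sample rate
  fit0 <- logistic_fit(data.frame(row.names = seq_along(y))[, 0, drop = FALSE],
                       y)
  expect_equal(plogis(fit0$coefficients$estimate[1]), mean(y),
               tolerance = 1e-8)
})

test_that("logistic_fit flags separation instead of silently diverging", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- x
  fit <- suppressWarnings(logistic_fit(matrix(x), y))
  expect_true(fit$separation)
  expect_error(logistic_fit(matrix(x), rep(1, 20)), "both levels")
})

test_that("null predictor at large n gives OR near 1", {
  set.seed(91)
  x <- rbinom(10000, 1, 0.5)
  y <- rbinom(10000, 1, 0.3)
  fit <- logistic_fit(matrix(x), y)
  expect_equal(fit$coefficients$or[2], 1, tolerance = 0.15)
})

test_that("anova_oneway matches its classical identities", {
  set.seed(92)
  v <- rnorm(40)
  g2 <- rep(c("a", "b"), 20)
  av <- anova_oneway(v, g2)
  tt <- t.test(v ~ g2, var.equal = TRUE)
  expect_equal(av$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(av$p, tt$p.value, tolerance = 1e-10)
  # zero within-variance, distinct means -> p ~ 0
  av0 <- anova_oneway(rep(c(1, 2, 3), each = 4), rep(1:3, each = 4))
  expect_lt(av0$p, 1e-12)
  expect_error(anova_oneway(v, rep("a", 40)), "2 groups")
  # against base R on 3 groups
  g3 <- rep(c("a", "b", "c"), length.out = 40)
  av3 <- anova_oneway(v, g3)
  ref <- oneway.test(v ~ g3, var.equal = TRUE)
  expect_equal(av3$f, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(av3$p, ref$p.value, tolerance = 1e-10)
})

test_that("homogeneity Q is zero on identical strata and detects inversion", {
  tab <- matrix(c(10, 20, 5, 30), 2, byrow = TRUE)
  r <- homogeneity_test(list(tab, tab, tab))
  expect_equal(r$q, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)
  expect_equal(r$df, 2)
  inv <- matrix(c(5, 30, 10, 20), 2, byrow = TRUE)
  strong <- matrix(c(40, 10, 5, 45), 2, byrow = TRUE)
  strong_inv <- matrix(c(5, 45, 40, 10), 2, byrow = TRUE)
  r2 <- homogeneity_test(list(strong, strong, strong_inv))
  expect_lt(r2$p, 0.05)
  expect_error(homogeneity_test(list(tab)), ">= 2")
  # zero cells get the +0.5 correction rather than failing
  zc <- matrix(c(0, 10, 5, 5), 2, byrow = TRUE)
  expect_silent(homogeneity_test(list(zc, tab)))
})

test_that("cohorts under a common odds ratio look homogeneous", {
  set.seed(93)
  pvals <- replicate(200, {
    tabs <- lapply(1:5, function(i) {
      n1 <- 20; n2 <- 40
      a <- rbinom(1, n1, 0.35); c <- rbinom(1, n2, 0.09)
      matrix(c(a, n1 - a, c, n2 - c), 2, byrow = TRUE)
    })
    homogeneity_test(tabs)$p
  })
  # p should be roughly uniform: no excess of small values
  expect_lt(abs(mean(pvals < 0.1) - 0.1), 0.07)
  expect_gt(mean(pvals), 0.4)
})
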