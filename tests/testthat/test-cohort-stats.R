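test_that("pooled proportions reproduce direct arithmetic", {
  expect_equal(round(100 * pooled_proportion(list(c(0, 24), c(5, 25))), 1),
               10.2)
  expect_equal(round(100 * pooled_proportion(list(c(5, 16), c(25, 37),
                                                  c(25, 26))), 1), 69.6)
  expect_equal(pooled_proportion(list(c(0, 50))), 0)
  expect_error(pooled_proportion(list(c(0, 0))), "zero")
  expect_error(pooled_proportion(list(c(5, 4))))
})

test_that("pooled mean/sd agrees with computation on concatenated raw data", {
  set.seed(12)
  g1 <- rnorm(14, 300, 40); g2 <- rnorm(23, 420, 90); g3 <- rnorm(9, 380, 60)
  groups <- data.frame(n = c(14, 23, 9),
                       mean = c(mean(g1), mean(g2), mean(g3)),
                       sd = c(sd(g1), sd(g2), sd(g3)))
  pooled <- pooled_mean_sd(groups)
  raw <- c(g1, g2, g3)
  expect_equal(pooled$mean, mean(raw), tolerance = 1e-12)
  expect_equal(pooled$sd, sd(raw), tolerance = 1e-12)
  single <- pooled_mean_sd(data.frame(n = 10, mean = 5, sd = 2))
  expect_equal(single$mean, 5)
  expect_equal(single$sd, 2)
})

test_that("group CST means pool to the published two-group values", {
  dry <- pooled_mean_sd(data.frame(n = c(24, 25), mean = c(304.4, 385.2),
                                   sd = c(42.7, 80.4)))
  wet <- pooled_mean_sd(data.frame(n = c(16, 37, 26),
                                   mean = c(420.8, 407.9, 493.5),
                                   sd = c(82.4, 129.0, 106.0)))
  expect_lt(abs(dry$mean - 345.65), 0.1)
  expect_lt(abs(wet$mean - 438.69), 0.1)
})

test_that("the chi-squared statistic equals the brute-force sum over cells", {
  tab <- matrix(c(5, 44, 55, 24), 2, byrow = TRUE)
  res <- chi_square_independence(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expected)^2 / expected),
               tolerance = 1e-12)
  expect_equal(res$df, 1, ignore_attr = TRUE)
  expect_lt(res$p, 0.001)
  # a table equal to its independence expectation gives statistic 0, p 1
  indep <- outer(c(20, 30), c(10, 40)) / 50
  res0 <- chi_square_independence(indep)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)
  expect_equal(chi_square_independence(matrix(10, 2, 2))$statistic, 0)
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("summary-statistic t tests match t.test on raw data", {
  set.seed(5)
  x <- rnorm(12, 10, 2); y <- rnorm(17, 11.5, 3)
  sx <- list(n = 12, mean = mean(x), sd = sd(x))
  sy <- list(n = 17, mean = mean(y), sd = sd(y))
  pooled <- two_sample_t(sx, sy, "pooled")
  ref_p <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$t, unname(ref_p$statistic), tolerance = 1e-12)
  expect_equal(pooled$p, ref_p$p.value, tolerance = 1e-12)
  welch <- two_sample_t(sx, sy, "welch")
  ref_w <- t.test(x, y)
  expect_equal(welch$t, unname(ref_w$statistic), tolerance = 1e-12)
  expect_equal(welch$df, unname(ref_w$parameter), tolerance = 1e-9)
  same <- list(n = 10, mean = 3, sd = 1)
  expect_equal(two_sample_t(same, same)$t, 0)
  expect_equal(two_sample_t(same, same)$p, 1)
})

test_that("the pooled t test agrees with a permutation oracle", {
  set.seed(8)
  x <- rnorm(10, 0, 1); y <- rnorm(10, 0.9, 1)
  res <- two_sample_t(list(n = 10, mean = mean(x), sd = sd(x)),
                      list(n = 10, mean = mean(y), sd = sd(y)))
  pool <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  perm <- replicate(4000, {
    idx <- sample(20, 10)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(res$p - p_perm), 0.06)
})

test_that("two-group ANOVA satisfies F = t^2 and KW matches the rank formula", {
  set.seed(3)
  a <- rnorm(9, 5, 1); b <- rnorm(14, 6, 1)
  fres <- anova_oneway(list(a, b))
  tres <- two_sample_t(list(n = 9, mean = mean(a), sd = sd(a)),
                       list(n = 14, mean = mean(b), sd = sd(b)), "pooled")
  expect_equal(fres$F, tres$t^2, tolerance = 1e-10)
  expect_equal(fres$p, tres$p, tolerance = 1e-10)

  groups <- list(c(1, 5, 8), c(2, 9, 11, 14), c(3, 6))  # rank-distinct
  kw <- kruskal_wallis(groups)
  values <- unlist(groups)
  N <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, function(v) length(v) * (mean(v) - (N + 1) / 2)^2))
  expect_equal(kw$H, H, tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$H, 0)
})

test_that("logistic regression recovers a known effect and the 2x2 identity", {
  # parameter recovery at n = 500, beta = 1.5
  set.seed(14)
  x <- rnorm(500)
  pr <- 1 / (1 + exp(-(-0.5 + 1.5 * x)))
  yv <- rbinom(500, 1, pr)
  fit <- logistic_regression(yv, data.frame(x = x))
  expect_false(fit$separated)
  est <- fit$coefficients$estimate[fit$coefficients$term == "x"]
  expect_lt(abs(est - 1.5), 0.3)

  # single binary predictor: OR equals the cross-product ratio
  xb <- rep(c(0, 1), times = c(60, 60))
  yb <- c(rbinom(60, 1, 0.25), rbinom(60, 1, 0.6))
  tab <- table(xb, yb)
  fit2 <- logistic_regression(yb, data.frame(x = xb))
  or_hat <- fit2$coefficients$or[fit2$coefficients$term == "x"]
  or_tab <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_equal(or_hat, unname(or_tab), tolerance = 1e-6)

  # perfect separation is flagged, no estimates returned
  xs <- c(rep(0, 20), rep(1, 20))
  fit3 <- logistic_regression(xs, data.frame(x = xs * 10 - 5))
  expect_true(fit3$separated)
  expect_null(fit3$coefficients)
})

test_that("Wald intervals cover the null when there is no effect", {
  set.seed(30)
  covered <- replicate(100, {
    x <- rnorm(60)
    yv <- rbinom(60, 1, 0.4)
    fit <- logistic_regression(yv, data.frame(x = x))
    if (fit$separated) return(NA)
    row <- fit$coefficients[fit$coefficients$term == "x", ]
    row$ci_low <= 1 && 1 <= row$ci_high
  })
  expect_gte(mean(covered, na.rm = TRUE), 0.9)
})

test_that("the cohort report reproduces group structure and test mapping", {
  co <- simulate_cohort(seed = 44)
  rep <- table2_report(co)
  expect_identical(sum(rep$per_type$n), nrow(co))
  expect_equal(rep$per_type$pct, 100 * rep$per_type$n / nrow(co))
  expect_identical(rep$per_type$type, observed_types())
  expect_true(all(c("age", "sex", "bcva", "ez", "cst", "erm") %in%
                    names(rep$tests)))
  expect_true(rep$pooled$ez_proportion[["wet"]] >
                rep$pooled$ez_proportion[["dry"]])
  # a single-eye cohort yields a degenerate report without tests
  solo <- co[1, ]
  rep1 <- table2_report(solo)
  expect_identical(rep1$n_total, 1L)
  expect_length(rep1$tests, 0L)
  expect_null(rep1$pooled)
  # determinism of the simulator
  expect_identical(simulate_cohort(seed = 44), co)
})
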