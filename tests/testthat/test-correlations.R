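test_that("pearson correlation matches a brute-force sum-of-products oracle", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.1, 0.7)
  y <- c(2.0, 3.9, 2.5, 6.3, 3.8, 1.1)
  n <- length(x)
  r_oracle <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  res <- cor_pearson(x, y)
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  # and against the standard implementation
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p.value, ct$p.value, tolerance = 1e-12)
})

test_that("perfectly linear data give r = 1 and zero variance errors out", {
  x <- 1:10
  expect_equal(cor_pearson(x, 2 * x + 1)$r, 1)
  expect_error(cor_pearson(x, rep(3, 10)), "variance")
})

test_that("independent data show near-zero correlation at large n", {
  set.seed(3)
  x <- rnorm(1000)
  y <- rnorm(1000)
  expect_lt(abs(cor_pearson(x, y)$r), 0.1)
})

test_that("partial correlation agrees with an lm-residual oracle", {
  set.seed(21)
  n <- 60
  Z <- cbind(z1 = rnorm(n), z2 = runif(n))
  x <- 0.5 * Z[, 1] + rnorm(n)
  y <- -0.3 * Z[, 2] + 0.4 * x + rnorm(n)
  res <- cor_partial(x, y, Z)
  rx <- resid(lm(x ~ Z))
  ry <- resid(lm(y ~ Z))
  expect_equal(res$r, cor(rx, ry), tolerance = 1e-12)
  expect_equal(res$df, n - 4L)
  # p-value consistent with the t transform
  expect_equal(res$p.value,
               2 * pt(-abs(res$r * sqrt(res$df / (1 - res$r^2))), res$df))
})

test_that("the headline coefficient reproduces its published p-value", {
  p <- partial_cor_pvalue(-0.52, n = 35, k = 2)
  expect_equal(round(p, 3), 0.002)
  t_stat <- -0.52 * sqrt(31 / (1 - 0.52^2))
  expect_equal(t_stat, -3.39, tolerance = 1e-3)
  expect_equal(p, t_pvalue_quadrature(t_stat, 31), tolerance = 1e-8)
})

test_that("with no covariates the partial correlation reduces to Pearson", {
  set.seed(5)
  x <- rnorm(30)
  y <- rnorm(30)
  expect_equal(cor_partial(x, y), cor_pearson(x, y))
})

test_that("conditioning on the common cause removes a spurious correlation", {
  set.seed(9)
  n <- 500
  z <- rnorm(n)
  x <- 2 * z + rnorm(n)
  y <- -1.5 * z + rnorm(n)
  marginal <- cor_pearson(x, y)$r
  partial <- cor_partial(x, y, cbind(z = z))$r
  expect_lt(marginal, -0.5)
  expect_lt(abs(partial), 0.15)
})

test_that("partial correlation is invariant to affine covariate transforms", {
  set.seed(13)
  n <- 40
  Z <- cbind(a = rnorm(n), b = rnorm(n))
  x <- rnorm(n) + Z[, 1]
  y <- rnorm(n) - Z[, 2]
  r1 <- cor_partial(x, y, Z)$r
  r2 <- cor_partial(x, y, cbind(10 * Z[, 1] - 3, -0.5 * Z[, 2] + 7))$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("rank-deficient covariates fail naming the offending column", {
  set.seed(17)
  n <- 30
  z <- rnorm(n)
  Z <- cbind(z1 = z, z2 = 2 * z)
  expect_error(cor_partial(rnorm(n), rnorm(n), Z), "z2")
})

test_that("pooled t test matches the hand formula on a 3-vs-3 example", {
  a <- c(1.0, 2.0, 3.0)
  b <- c(2.5, 3.5, 5.1)
  res <- t_test_groups(a, b)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$p.value, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-12)
})

test_that("identical groups give t = 0 and p = 1", {
  res <- t_test_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
})

test_that("the sex difference in duct length is detected in most replicates", {
  set.seed(19)
  hits <- vapply(1:200, function(i) {
    m <- rnorm(15, 34.6, 0.9)
    f <- rnorm(29, 33.6, 1.5)
    t_test_groups(m, f)$p.value < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.5)
})

test_that("Bonferroni thresholds follow alpha / m", {
  expect_equal(bonferroni_threshold(0.05, 12), 0.05 / 12)
  expect_equal(round(bonferroni_threshold(0.05, 12), 4), 0.0042)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_error(bonferroni_threshold(0.05, 0), "positive integer")
})

test_that("p-values agree with numeric t-density integration across cases", {
  grid <- expand.grid(r = c(-0.75, -0.3, 0.2, 0.6), n = c(20, 35, 60))
  for (i in seq_len(nrow(grid))) {
    r <- grid$r[i]; n <- grid$n[i]; k <- 2
    p <- partial_cor_pvalue(r, n, k)
    t_stat <- r * sqrt((n - 2 - k) / (1 - r^2))
    expect_equal(p, t_pvalue_quadrature(t_stat, n - 2 - k), tolerance = 1e-8)
  }
})
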