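#' Pearson correlation with a t-based test
#'
#' Product-moment correlation between two vectors, with the two-sided
#' p-value from the exact t transform `t = r * sqrt(df / (1 - r^2))`,
#' `df = n - 2`. Returned as a one-row tibble so results for many variable
#' pairs stack naturally.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), no missing values,
#'   non-zero variance.
#' @param alpha Significance level. Default 0.05.
#' @param m Number of tests in the family for the Bonferroni flag.
#'   Default 1.
#' @return A one-row tibble: `r`, `n`, `k` (number of covariates, 0 here),
#'   `df`, `statistic`, `p.value`, `significant_raw`,
#'   `significant_bonferroni`.
#' @examples
#' cor_pearson(1:10, (1:10)^2)
#' @export
cor_pearson <- function(x, y, alpha = 0.05, m = 1) {
  cor_partial(x, y, covariates = NULL, alpha = alpha, m = m)
}

#' Covariate-adjusted partial correlation
#'
#' Partial correlation of `x` and `y` controlling for covariates, computed
#' by residualisation: each of `x` and `y` is regressed (with intercept) on
#' the covariates and the Pearson correlation of the residuals is taken.
#' The two-sided p-value uses `t = r * sqrt(df / (1 - r^2))` with
#' `df = n - 2 - k` for `k` covariates. With no covariates this reduces to
#' the ordinary Pearson test.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix or data frame with one row per
#'   observation; must be full rank together with the intercept.
#' @param alpha Significance level. Default 0.05.
#' @param m Number of tests in the family for the Bonferroni flag.
#'   Default 1.
#' @return A one-row tibble as in [cor_pearson()].
#' @examples
#' set.seed(1)
#' z <- rnorm(50)
#' cor_partial(z + rnorm(50), z + rnorm(50), covariates = cbind(z = z))
#' @export
cor_partial <- function(x, y, covariates = NULL, alpha = 0.05, m = 1) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have the same length")
  if (anyNA(x) || anyNA(y)) abort("missing values in `x` or `y`; apply listwise deletion first")

  if (is.null(covariates) || NCOL(covariates) == 0) {
    k <- 0L
    rx <- x - mean(x)
    ry <- y - mean(y)
  } else {
    Z <- as.matrix(covariates)
    if (nrow(Z) != n) abort("`covariates` must have one row per observation")
    if (anyNA(Z)) abort("missing values in `covariates`")
    k <- ncol(Z)
    if (n < k + 4) abort("need n >= k + 4 observations")
    X <- cbind(`(intercept)` = 1, Z)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dropped <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
      abort(paste0("covariates are rank deficient; offending column(s): ",
                   paste(dropped, collapse = ", ")))
    }
    rx <- qr.resid(qx, x)
    ry <- qr.resid(qx, y)
  }
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("zero residual variance; correlation undefined")
  }
  r <- cor(rx, ry)
  df <- n - 2L - k
  if (df < 1) abort("non-positive degrees of freedom")
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(t_stat), df)
  tibble(
    r = r, n = n, k = as.integer(k), df = as.integer(df),
    statistic = t_stat, p.value = p,
    significant_raw = p < alpha,
    significant_bonferroni = p < alpha / m
  )
}

#' Two-sided p-value for a given partial correlation
#'
#' Converts a partial correlation coefficient to its two-sided p-value via
#' the t transform `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - k`.
#' Useful for checking reported coefficient/p-value pairs.
#'
#' @param r Partial correlation coefficient.
#' @param n Sample size.
#' @param k Number of covariates controlled for.
#' @return Two-sided p-value.
#' @examples
#' partial_cor_pvalue(-0.52, n = 35, k = 2) # ~0.002
#' @export
partial_cor_pvalue <- function(r, n, k = 0) {
  if (any(abs(r) >= 1)) abort("`r` must lie strictly inside (-1, 1)")
  df <- n - 2 - k
  if (any(df < 1)) abort("non-positive degrees of freedom")
  t_stat <- r * sqrt(df / (1 - r^2))
  2 * pt(-abs(t_stat), df)
}

#' Two-sample t test as a tidy one-row tibble
#'
#' Student's pooled-variance two-sample t test by default (Welch's
#' correction behind the `welch` flag), as used for comparing cochlear
#' parameters between sexes and sides.
#'
#' @param a,b Numeric vectors, each with at least two observations.
#' @param welch Use the Welch (unequal variance) test? Default `FALSE`.
#' @return A one-row tibble: `estimate` (mean of `a` minus mean of `b`),
#'   `statistic`, `df`, `p.value`, `method`.
#' @export
t_test_groups <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("each group needs at least 2 observations")
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    # degenerate equal constants: define t = 0, p = 1
    return(tibble(estimate = 0, statistic = 0,
                  df = length(a) + length(b) - 2, p.value = 1,
                  method = if (welch) "welch" else "student"))
  }
  tt <- t.test(a, b, var.equal = !welch)
  tibble(
    estimate = unname(diff(rev(tt$estimate))),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    method = if (welch) "welch" else "student"
  )
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise error control by dividing the significance level by the
#' number of tests. For the default speech-outcome family (4 measures x
#' 3 time points) the corrected threshold is 0.05 / 12, printed as 0.0042.
#'
#' @param alpha Family-wise level. Default 0.05.
#' @param m Number of tests. Default 12.
#' @return The corrected per-test threshold `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 12)
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 12) {
  if (m < 1 || m != round(m)) abort("`m` must be a positive integer")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  alpha / m
}
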