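# Cohort-level summary statistics: OLS r^2, Spearman rank correlation and
# the Welch unequal-variance t test, each returned in a uniform record.
# Raw p-values are reported; no multiple-testing correction is applied.

.statResult <- function(method, statistic, p, n) {
  data.frame(method = method, statistic = statistic, p_value = p, n = n,
             stringsAsFactors = FALSE)
}

#' Linear regression r-squared
#'
#' Ordinary least squares of y on x; reports r^2 and the two-sided p-value
#' of the slope.
#'
#' @param x,y finite numeric vectors, n >= 3; x must vary.
#' @return one-row data.frame: `method`, `statistic` (r^2), `p_value`, `n`.
#' @examples
#' linearRegressionR2(1:10, 2 * (1:10) + 1)$statistic   # 1
#' @export
linearRegressionR2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite observations")
  if (stats::var(x) == 0) stop("zero variance in x: regression undefined")
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))   # exact fits warn harmlessly
  p <- if (s$sigma == 0) 0 else s$coefficients["x", "Pr(>|t|)"]
  .statResult("ols_r2", s$r.squared, p, length(x))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), with a
#' two-sided p-value from the t approximation.
#'
#' @param x,y finite numeric vectors, n >= 3; neither may be all-tied.
#' @return one-row data.frame: `method`, `statistic` (r), `p_value`, `n`.
#' @examples
#' spearmanR(1:8, exp(1:8))$statistic   # 1: monotone
#' @export
spearmanR <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("all-tied vector: Spearman correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  .statResult("spearman", unname(ct$estimate), ct$p.value, length(x))
}

#' Welch two-sample t test
#'
#' Two-tailed two-sample t test with unequal variances
#' (Welch-Satterthwaite degrees of freedom).
#'
#' @param a,b numeric vectors, each with n >= 2.
#' @return one-row data.frame: `method`, `statistic` (t), `p_value`, `n`
#'   (total).
#' @export
welchTTest <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      stop("zero variance in both groups with equal means: t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  .statResult("welch_t", unname(tt$statistic), tt$p.value,
              length(a) + length(b))
}
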