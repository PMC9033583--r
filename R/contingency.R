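#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by full hypergeometric enumeration with both
#' margins fixed: the p-value is the sum of probabilities of all tables at
#' least as unlikely as the observed one (minimum-likelihood convention,
#' with a 1 + 1e-7 relative tolerance when comparing probabilities).
#' Degenerate margins give p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a length-4
#'   vector (a, b, c, d) filled by row.
#' @return list with `p_value`, `odds_ratio` (sample ad/bc, possibly
#'   infinite), and the observed `table`.
#' @export
fisher_exact <- function(tab) {
  tab <- as_2x2(tab)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || n == 0 || k == 0 || k == m + n)
    return(list(p_value = 1, odds_ratio = NaN, table = tab))
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  p <- sum(dens[dens <= obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = min(p, 1), odds_ratio = or, table = tab)
}

#' Pearson chi-square test for an R x C table
#'
#' Classical Pearson statistic sum((O - E)^2 / E) with E the product-margin
#' expectations, df = (R-1)(C-1), no continuity correction. Tables with a
#' zero row or column margin are an error.
#'
#' @param tab matrix of non-negative counts with at least 2 rows and columns.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || anyNA(tab)) stop("counts must be non-negative")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2x2 table")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin")
  E <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), expected = E)
}

as_2x2 <- function(tab) {
  if (!is.matrix(tab)) {
    if (length(tab) != 4) stop("expected a 2x2 table")
    tab <- matrix(tab, 2, 2, byrow = TRUE)
  }
  if (!all(dim(tab) == 2)) stop("expected a 2x2 table")
  if (any(tab < 0) || anyNA(tab)) stop("counts must be non-negative")
  if (any(tab != round(tab))) stop("counts must be integer")
  tab
}

#' Pearson and Spearman correlation with t-approximation p-values
#'
#' Pearson's r with the exact t-test on n - 2 df; Spearman's rho computed as
#' Pearson on midranks, with the same t-approximation for its p-value.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite, non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate`, `statistic` (t), `df`, `p_value`, `method`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  list(estimate = r, statistic = tt, df = n - 2,
       p_value = 2 * stats::pt(-abs(tt), df = n - 2), method = method)
}
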