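#' @title Statistical primitives
#' @description Convention-fixed wrappers around the classical tests used
#'   throughout the pipeline (two-sample Kolmogorov-Smirnov, Spearman rank
#'   correlation, one-way fixed-effects ANOVA, Student's t), plus the
#'   percentile convention shared by normalization and band filters. Each
#'   returns a `test_result` so downstream code and the JSON report handle
#'   them uniformly, and each documents its degenerate-input rules.
#' @name stats-primitives
NULL

#' Construct a test result
#'
#' @param statistic test statistic (may be `NA` when undefined).
#' @param p_value probability in \[0, 1\] (or `NA` when undefined).
#' @param n integer vector of per-group sample sizes.
#' @param method short label naming the test.
#' @param note optional flag describing a degenerate case.
#' @return An object of class `test_result`.
#' @export
test_result <- function(statistic, p_value, n, method, note = NA_character_) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value outside [0, 1]")
  }
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         n = unname(n), method = method, note = note),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (n = %s)%s\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = ", "),
              if (is.na(x$note)) "" else paste0(" [", x$note, "]")))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-tailed comparison of empirical distribution functions,
#' D = sup |ECDF_x - ECDF_y|. The p-value is computed exactly (by the
#' Smirnov distribution, equivalent to enumeration over label assignments,
#' ties included) when `n * m <= 10^4`, and otherwise by the asymptotic
#' Kolmogorov distribution with effective size `n * m / (n + m)`.
#'
#' @param x,y numeric vectors (non-empty).
#' @return A [test_result] with the D statistic.
#' @export
ks_two_sample <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop("ks_two_sample: empty input")
  exact <- length(x) * length(y) <= 1e4
  res <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  test_result(res$statistic, min(1, res$p.value), c(length(x), length(y)),
              "two-sample Kolmogorov-Smirnov (two-tailed)",
              note = if (exact) "exact" else "asymptotic")
}

#' Spearman rank correlation
#'
#' Pearson correlation of average (midrank) ranks; two-tailed p-value from
#' the t approximation with n - 2 degrees of freedom. A constant input
#' vector leaves the correlation undefined: rho and p are `NA` and the
#' result is flagged.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return A [test_result]; `statistic` is rho.
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("spearman_rho: length mismatch")
  n <- length(x)
  if (n < 3L) stop("spearman_rho: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(test_result(NA_real_, NA_real_, n, "Spearman rank correlation",
                       note = "undefined: constant input"))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  test_result(rho, p, n, "Spearman rank correlation")
}

#' One-way fixed-effects ANOVA
#'
#' Classical F test by direct sum-of-squares decomposition. Degenerate
#' rules: zero within-group and zero between-group variance gives F = 0,
#' p = 1; zero within-group variance with distinct group means gives
#' F = Inf, p = 0, flagged.
#'
#' @param groups list of numeric vectors, >= 2 groups.
#' @return A [test_result]; `statistic` is F.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("one_way_anova: need a list of >= 2 groups")
  }
  groups <- lapply(groups, as.numeric)
  ns <- lengths(groups)
  if (any(ns < 1L)) stop("one_way_anova: empty group")
  k <- length(groups)
  n <- sum(ns)
  if (n <= k) stop("one_way_anova: no residual degrees of freedom")
  gm <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / n
  ssb <- sum(ns * (gm - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- n - k
  if (ssw == 0 && ssb == 0) {
    return(test_result(0, 1, ns, "one-way ANOVA", note = "all values equal"))
  }
  if (ssw == 0) {
    return(test_result(Inf, 0, ns, "one-way ANOVA",
                       note = "zero within-group variance"))
  }
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  test_result(f, p, ns, "one-way ANOVA")
}

#' Two-tailed Student's t test
#'
#' Equal-variance pooled t by default; `welch = TRUE` drops the
#' equal-variance assumption. With zero variance in both groups and equal
#' means the difference is identically zero: t = 0, p = 1.
#'
#' @param x,y numeric vectors, n >= 2 each (paired: equal lengths).
#' @param paired treat samples as paired differences.
#' @param welch use the Welch-Satterthwaite approximation.
#' @return A [test_result]; `statistic` is t.
#' @export
t_test_two_tailed <- function(x, y, paired = FALSE, welch = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stop("t_test_two_tailed: need n >= 2")
  degenerate <- if (paired) {
    stats::sd(x - y) == 0 && mean(x - y) == 0
  } else {
    stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)
  }
  if (degenerate) {
    return(test_result(0, 1, c(length(x), length(y)),
                       "Student's t (two-tailed)", note = "zero variance"))
  }
  res <- stats::t.test(x, y, paired = paired, var.equal = !welch,
                       alternative = "two.sided")
  test_result(res$statistic, res$p.value, c(length(x), length(y)),
              if (welch) "Welch's t (two-tailed)" else "Student's t (two-tailed)")
}

#' Percentile under the linear-interpolation convention
#'
#' Quantile at position h = (n - 1) q on the sorted values with linear
#' interpolation between order statistics (R's `quantile` type 7). This
#' single convention is used everywhere a percentile appears
#' (upper-quartile normalization, 3'UTR inter-quartile band).
#'
#' @param values non-empty numeric vector.
#' @param q probability (or vector of probabilities) in \[0, 1\].
#' @return Numeric value(s).
#' @export
percentile <- function(values, q) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("percentile: empty input")
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}

#' Benjamini-Hochberg adjustment (optional helper)
#'
#' @param p vector of p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
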