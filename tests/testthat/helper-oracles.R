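# Brute-force oracles, independent of the implementation paths they check.

# every 6-substring compared against the motif set
oracle_scan <- function(seq, hexamers) {
  seq <- chartr("U", "T", toupper(seq))
  n <- nchar(seq)
  if (n < 6L) return(data.frame(offset = integer(0), motif = character(0)))
  subs <- substring(seq, 1:(n - 5L), 6:n)
  hit <- subs %in% hexamers
  data.frame(offset = which(hit) - 1L, motif = subs[hit],
             stringsAsFactors = FALSE)
}

# percentile by the h = (n-1)q definition, written out
oracle_percentile <- function(v, q) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * q
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  v[lo] + (h - floor(h)) * (v[hi] - v[lo])
}

# two-sample K-S statistic from ECDFs evaluated on the pooled support
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
}

# exact two-sided K-S p by full enumeration over label assignments
oracle_ks_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  d_obs <- oracle_ks_D(x, y)
  idx <- utils::combn(length(pooled), n)
  d_all <- apply(idx, 2, function(ix) oracle_ks_D(pooled[ix], pooled[-ix]))
  list(D = d_obs, p = mean(d_all >= d_obs - 1e-12))
}

# Spearman rho via explicit average ranks and the Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# pooled-variance two-sample t, written out
oracle_t_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, p = 2 * stats::pt(-abs(tt), nx + ny - 2))
}

# OLS slope/intercept by the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# classical two-slope t statistic (pooled residual variance)
oracle_two_slope_t <- function(x1, y1, x2, y2) {
  f1 <- stats::lm(y1 ~ x1)
  f2 <- stats::lm(y2 ~ x2)
  rss <- sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)
  df <- length(y1) + length(y2) - 4
  s2 <- rss / df
  se <- sqrt(s2 * (1 / sum((x1 - mean(x1))^2) + 1 / sum((x2 - mean(x2))^2)))
  (stats::coef(f1)[2] - stats::coef(f2)[2]) / se
}

# per-base walk: genomic positions of a transcript's 3'UTR in transcript order
oracle_utr_bases <- function(t) {
  iv <- t$utr3_intervals
  pos <- unlist(lapply(seq_len(nrow(iv)), function(i) iv[i, 1]:(iv[i, 2] - 1)))
  if (t$strand == "-") rev(pos) else pos
}
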