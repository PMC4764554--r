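#' @title 3'UTR count-matrix normalization and protection-set classification
#' @description The normalization pipeline is order-fixed: RPKM ->
#'   upper-quartile (75th percentile) scaling -> log2(x + pseudocount).
#'   Genes with fewer than 25 3'UTR-mapped reads in total are removed
#'   before analysis. Differential condition effects are tested per gene by
#'   one-way ANOVA across the four knockdown conditions; "reproducible"
#'   regulation additionally requires an identical fold-change sign in
#'   every replicate pairing.
#' @name expression
NULL

.conditions <- c("siNT", "siUPF1", "siPTBP1", "siPTBP1_siUPF1")

#' Build a count table
#'
#' @param counts non-negative integer matrix, genes x samples; rownames are
#'   gene ids, colnames sample ids.
#' @param design data frame with columns `sample`, `condition` (one of
#'   siNT, siUPF1, siPTBP1, siPTBP1_siUPF1) and `replicate`.
#' @return Object of class `count_table`.
#' @export
count_table <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  stopifnot(all(c("sample", "condition", "replicate") %in% names(design)))
  if (!setequal(design$sample, colnames(counts))) {
    stop("design samples do not match count columns")
  }
  design <- design[match(colnames(counts), design$sample), ]
  bad <- setdiff(unique(design$condition), .conditions)
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (any(table(factor(design$condition, .conditions)) < 1L)) {
    stop("every condition needs at least one replicate")
  }
  structure(list(counts = counts, design = design), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table: %d genes x %d samples (%s)>\n",
              nrow(x$counts), ncol(x$counts),
              paste(table(x$design$condition), collapse = "/")))
  invisible(x)
}

#' Remove genes with few 3'UTR-mapped reads
#'
#' Genes whose total read count across all samples is below `min_reads`
#' (default 25) are removed.
#'
#' @param ct a [count_table].
#' @param min_reads threshold; genes with total < `min_reads` are dropped.
#' @return Filtered [count_table].
#' @export
filter_low_counts <- function(ct, min_reads = 25) {
  stopifnot(inherits(ct, "count_table"))
  keep <- rowSums(ct$counts) >= min_reads
  if (!any(keep)) warning("all genes fall below the read-count threshold")
  ct$counts <- ct$counts[keep, , drop = FALSE]
  ct
}

#' Reads per kilobase of 3'UTR per million mapped reads
#'
#' `rpkm[g, s] = counts[g, s] / (length[g]/1000) / (libsize[s]/1e6)`.
#' Library size defaults to the per-sample total of 3'UTR-mapped reads
#' (the column sum); an externally supplied total-mapped count may be
#' passed instead. Genes without a length are dropped with a warning.
#'
#' @param ct a [count_table].
#' @param lengths named vector of 3'UTR lengths (nt), keyed by gene id.
#' @param libsize optional named vector of per-sample library sizes.
#' @return Numeric matrix of RPKM values.
#' @export
compute_rpkm <- function(ct, lengths, libsize = NULL) {
  stopifnot(inherits(ct, "count_table"))
  genes <- rownames(ct$counts)
  have <- genes %in% names(lengths) & !is.na(lengths[genes])
  if (!all(have)) {
    warning(sprintf("dropping %d gene(s) without a 3'UTR length", sum(!have)))
  }
  counts <- ct$counts[have, , drop = FALSE]
  len <- as.numeric(lengths[rownames(counts)])
  if (any(len <= 0)) stop("3'UTR lengths must be positive")
  if (is.null(libsize)) {
    libsize <- colSums(ct$counts)
  } else {
    libsize <- as.numeric(libsize[colnames(counts)])
  }
  if (any(libsize <= 0)) stop("library sizes must be positive")
  sweep(counts / (len / 1000), 2, libsize / 1e6, "/")
}

#' Upper-quartile (75th percentile) normalization
#'
#' Each sample is divided by the 75th percentile of its positive values
#' (linear-interpolation convention, see [percentile()]) and multiplied by
#' the geometric mean of those percentiles across samples, preserving the
#' overall scale. Idempotent: applying it twice equals applying it once.
#'
#' @param m numeric matrix (genes x samples).
#' @return Normalized matrix.
#' @export
upper_quartile_normalize <- function(m) {
  m <- as.matrix(m)
  q75 <- apply(m, 2, function(v) {
    pos <- v[v > 0]
    if (length(pos) == 0L) stop("sample with no positive values")
    percentile(pos, 0.75)
  })
  sweep(m, 2, q75, "/") * exp(mean(log(q75)))
}

#' Log2 transformation with pseudocount
#'
#' @param m non-negative numeric matrix.
#' @param pseudocount small positive constant added before log2 (default 1).
#' @param design optional design data frame; when provided the result is a
#'   `normalized_table` (values + design), otherwise a plain matrix.
#' @return Matrix of `log2(x + pseudocount)` values, or a
#'   `normalized_table`.
#' @export
log2_transform <- function(m, pseudocount = 1, design = NULL) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative values in input")
  values <- log2(m + pseudocount)
  if (is.null(design)) return(values)
  normalized_table(values, design)
}

#' Construct a normalized expression table
#'
#' @param values finite numeric matrix of log2 normalized RPKM.
#' @param design design data frame as in [count_table()].
#' @return Object of class `normalized_table`.
#' @export
normalized_table <- function(values, design) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("normalized values must be finite")
  design <- design[match(colnames(values), design$sample), ]
  structure(list(values = values, design = design), class = "normalized_table")
}

#' Full normalization pipeline
#'
#' RPKM -> upper-quartile -> log2, in that fixed order.
#'
#' @inheritParams compute_rpkm
#' @param pseudocount passed to [log2_transform()].
#' @return A `normalized_table`.
#' @export
normalize_counts <- function(ct, lengths, libsize = NULL, pseudocount = 1) {
  rpkm <- compute_rpkm(ct, lengths, libsize)
  log2_transform(upper_quartile_normalize(rpkm), pseudocount, design = ct$design)
}

# all cross-pair differences of columns a over columns b: G x (na*nb)
.pair_diffs <- function(values, a_cols, b_cols) {
  pairs <- expand.grid(a = a_cols, b = b_cols)
  d <- vapply(seq_len(nrow(pairs)),
              function(i) values[, pairs$a[i]] - values[, pairs$b[i]],
              numeric(nrow(values)))
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(values))
  d
}

#' Per-gene differential test across the four knockdown conditions
#'
#' For every gene: a one-way fixed-effects ANOVA F test across siNT,
#' siUPF1, siPTBP1 and siPTBP1+siUPF1; mean log2 fold changes for the three
#' contrasts of interest (`fc_ptb` = siPTBP1 - siNT, `fc_rescue` = double
#' knockdown - siPTBP1, `fc_upf1` = siUPF1 - siNT); and per-replicate-pair
#' fold-change sign tallies over all cross pairings of replicates, used by
#' the reproducibility rule. Degenerate genes (zero within-group variance)
#' follow the rules of [one_way_anova()].
#'
#' @param nt a `normalized_table`.
#' @return Data frame of class `differential_result`, one row per gene,
#'   with columns `gene_id`, `fc_ptb`, `fc_rescue`, `fc_upf1`, `f_stat`,
#'   `p_anova`, `ptb_pairs_neg`, `ptb_pairs_pos`, `ptb_n_pairs`,
#'   `rescue_pairs_pos`, `rescue_pairs_neg`, `rescue_n_pairs`.
#' @export
differential_anova <- function(nt) {
  stopifnot(inherits(nt, "normalized_table"))
  v <- nt$values
  cond <- nt$design$condition
  cols <- lapply(.conditions, function(cc) which(cond == cc))
  names(cols) <- .conditions
  ns <- lengths(cols)
  if (any(ns < 2L)) stop("the F test needs >= 2 replicates per condition")
  G <- nrow(v)
  k <- length(cols)
  n <- sum(ns)
  means <- vapply(cols, function(ix) rowMeans(v[, ix, drop = FALSE]),
                  numeric(G))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = G, dimnames = list(NULL, .conditions))
  }
  grand <- rowSums(v[, unlist(cols), drop = FALSE]) / n
  ssb <- rowSums(sweep(means, 1, grand, "-")^2 %*% diag(ns))
  ssw <- Reduce(`+`, lapply(.conditions, function(cc) {
    sub <- v[, cols[[cc]], drop = FALSE]
    rowSums((sub - means[, cc])^2)
  }))
  df1 <- k - 1L
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  zero_both <- ssw < 1e-12 & ssb < 1e-12
  zero_within <- ssw < 1e-12 & !zero_both
  f[zero_both] <- 0; p[zero_both] <- 1
  f[zero_within] <- Inf; p[zero_within] <- 0

  ptb_d <- .pair_diffs(v, cols$siPTBP1, cols$siNT)
  res_d <- .pair_diffs(v, cols$siPTBP1_siUPF1, cols$siPTBP1)
  out <- data.frame(
    gene_id = rownames(v),
    fc_ptb = means[, "siPTBP1"] - means[, "siNT"],
    fc_rescue = means[, "siPTBP1_siUPF1"] - means[, "siPTBP1"],
    fc_upf1 = means[, "siUPF1"] - means[, "siNT"],
    f_stat = f, p_anova = p,
    ptb_pairs_neg = rowSums(ptb_d < 0), ptb_pairs_pos = rowSums(ptb_d > 0),
    ptb_n_pairs = ncol(ptb_d),
    rescue_pairs_pos = rowSums(res_d > 0), rescue_pairs_neg = rowSums(res_d < 0),
    rescue_n_pairs = ncol(res_d),
    degenerate = zero_both | zero_within,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("differential_result", class(out))
  out
}

#' Classify the down-regulated and rescued gene sets
#'
#' "Down" genes decreased reproducibly upon PTBP1 depletion: mean
#' `fc_ptb < 0`, ANOVA `p < alpha`, and a negative fold-change sign in
#' every replicate pairing of siPTBP1 against siNT. "Rescued" genes are the
#' subset of down genes that reproducibly increase in the double knockdown
#' relative to siPTBP1 alone (mean `fc_rescue > 0`, all pairings positive).
#'
#' @param d a `differential_result` from [differential_anova()].
#' @param alpha raw ANOVA p-value threshold (default 0.05; no
#'   multiple-testing correction is applied by default, use [bh_adjust()]
#'   upstream if desired).
#' @return Object of class `protection_sets`: `down_genes`,
#'   `rescued_genes` (a subset of `down_genes`), per-set mean fold-change
#'   `summary`, and `alpha`.
#' @export
classify_protection_sets <- function(d, alpha = 0.05) {
  stopifnot(inherits(d, "differential_result"))
  down_sel <- d$fc_ptb < 0 & d$p_anova < alpha &
    d$ptb_pairs_neg == d$ptb_n_pairs
  rescued_sel <- down_sel & d$fc_rescue > 0 &
    d$rescue_pairs_pos == d$rescue_n_pairs
  down <- d$gene_id[down_sel]
  rescued <- d$gene_id[rescued_sel]
  summarise <- function(sel) {
    if (!any(sel)) return(c(fc_ptb = NA_real_, fc_rescue = NA_real_,
                            fc_upf1 = NA_real_))
    c(fc_ptb = mean(d$fc_ptb[sel]), fc_rescue = mean(d$fc_rescue[sel]),
      fc_upf1 = mean(d$fc_upf1[sel]))
  }
  structure(
    list(down_genes = down, rescued_genes = rescued,
         summary = list(down = summarise(down_sel),
                        rescued = summarise(rescued_sel)),
         alpha = alpha),
    class = "protection_sets"
  )
}

#' @export
print.protection_sets <- function(x, ...) {
  cat(sprintf("<protection_sets: %d down-regulated, %d rescued (alpha = %g)>\n",
              length(x$down_genes), length(x$rescued_genes), x$alpha))
  invisible(x)
}

#' Rescue-versus-knockdown correlation over the down set
#'
#' Spearman's rho of `fc_rescue` against `fc_ptb` over the down-regulated
#' genes, overall and within hexamer-present / hexamer-absent strata, plus
#' the ordinary least-squares line for plotting. A stratum with fewer than
#' 3 genes has an undefined correlation and is flagged.
#'
#' @param d a `differential_result`.
#' @param down character vector of down-regulated gene ids.
#' @param strata optional named logical vector (gene id -> hexamer
#'   presence) used to stratify.
#' @return List with `overall` ([test_result]), `fit` (slope, intercept),
#'   and when strata are given `hexamer_present` / `hexamer_absent`
#'   results.
#' @export
rescue_correlation <- function(d, down, strata = NULL) {
  stopifnot(inherits(d, "differential_result"))
  sub <- d[d$gene_id %in% down, ]
  if (nrow(sub) < 3L) stop("need at least 3 down-regulated genes")
  out <- list(overall = spearman_rho(sub$fc_ptb, sub$fc_rescue))
  co <- stats::coef(stats::lm(fc_rescue ~ fc_ptb, data = sub))
  out$fit <- list(intercept = unname(co[1]), slope = unname(co[2]))
  if (!is.null(strata)) {
    flag <- strata[sub$gene_id]
    for (lv in c(TRUE, FALSE)) {
      nm <- if (lv) "hexamer_present" else "hexamer_absent"
      s <- sub[!is.na(flag) & flag == lv, ]
      out[[nm]] <- if (nrow(s) < 3L) {
        test_result(NA_real_, NA_real_, nrow(s), "Spearman rank correlation",
                    note = "undefined: fewer than 3 genes in stratum")
      } else {
        spearman_rho(s$fc_ptb, s$fc_rescue)
      }
    }
  }
  out
}

#' 3'UTR length distribution comparison
#'
#' ECDFs and medians of 3'UTR lengths per gene set, with two-tailed
#' Kolmogorov-Smirnov tests of each set against the reference set (by
#' default the first, conventionally all expressed exemplars).
#'
#' @param sets named list of numeric 3'UTR length vectors.
#' @param reference name of the reference set (default the first).
#' @return List with `ecdf` (list of ECDF functions), `medians`, and `ks`
#'   (data frame: set, n, D, p against the reference).
#' @export
utr_length_cdf <- function(sets, reference = names(sets)[1]) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  if (any(lengths(sets) == 0L)) stop("empty set")
  if (!reference %in% names(sets)) stop("unknown reference set")
  ref <- sets[[reference]]
  others <- setdiff(names(sets), reference)
  ks <- do.call(rbind, lapply(others, function(nm) {
    r <- ks_two_sample(sets[[nm]], ref)
    data.frame(set = nm, n = length(sets[[nm]]), D = r$statistic,
               p = r$p_value, stringsAsFactors = FALSE)
  }))
  list(
    ecdf = lapply(sets, stats::ecdf),
    medians = vapply(sets, stats::median, numeric(1)),
    ks = ks,
    reference = reference
  )
}
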