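test_that("RPKM follows its defining formula and scale invariance", {
  counts <- matrix(10, 1, 12, dimnames = list("G1", NULL))
  ct <- toy_count_table(counts)
  r <- compute_rpkm(ct, c(G1 = 1000), libsize = setNames(rep(1e6, 12),
                                                         colnames(ct$counts)))
  expect_true(all(r == 10))
  r2 <- compute_rpkm(ct, c(G1 = 500),
                     libsize = setNames(rep(2e6, 12), colnames(ct$counts)))
  ct25 <- toy_count_table(matrix(25, 1, 12, dimnames = list("G1", NULL)))
  expect_equal(unname(compute_rpkm(ct25, c(G1 = 500),
    libsize = setNames(rep(2e6, 12), colnames(ct$counts)))[1, 1]), 25)
  # joint doubling of counts and library size cancels
  ctx <- toy_count_table(matrix(rpois(24, 40), 2, 12,
                                dimnames = list(c("G1", "G2"), NULL)))
  lens <- c(G1 = 700, G2 = 1300)
  lib <- setNames(runif(12, 1e6, 2e6), colnames(ctx$counts))
  ctx2 <- ctx; ctx2$counts <- ctx$counts * 2
  expect_equal(compute_rpkm(ctx, lens, lib),
               compute_rpkm(ctx2, lens, 2 * lib))
  # genes without a length are dropped with a warning
  expect_warning(r3 <- compute_rpkm(ctx, c(G1 = 700)), "without")
  expect_equal(rownames(r3), "G1")
})

test_that("upper-quartile normalization equalizes positive 75th percentiles and is idempotent", {
  set.seed(31)
  m <- matrix(rlnorm(200, 3, 1), 50, 4)
  m[sample(200, 20)] <- 0
  n1 <- upper_quartile_normalize(m)
  q <- apply(n1, 2, function(v) percentile(v[v > 0], 0.75))
  expect_equal(max(q) - min(q), 0, tolerance = 1e-12)
  expect_equal(upper_quartile_normalize(n1), n1, tolerance = 1e-12)
  # two identical samples stay identical
  mm <- cbind(m[, 1], m[, 1])
  expect_equal(upper_quartile_normalize(mm), mm)
  expect_error(upper_quartile_normalize(cbind(c(0, 0), c(1, 2))), "positive")
})

test_that("log2 transform applies the pseudocount and rejects negatives", {
  expect_equal(log2_transform(matrix(c(0, 1, 7))), matrix(c(0, 1, 3)))
  expect_error(log2_transform(matrix(-1)), "negative")
  expect_error(log2_transform(matrix(1), pseudocount = 0), "positive")
})

test_that("low-count filtering removes genes below the read threshold", {
  counts <- matrix(0, 3, 12, dimnames = list(c("A", "B", "C"), NULL))
  counts[1, 1] <- 24; counts[2, 1] <- 25; counts[3, 1] <- 100
  ct <- toy_count_table(counts)
  expect_equal(rownames(filter_low_counts(ct, 25)$counts), c("B", "C"))
  expect_equal(rownames(filter_low_counts(ct, 0)$counts), c("A", "B", "C"))
  expect_warning(e <- filter_low_counts(ct, 1000), "threshold")
  expect_equal(nrow(e$counts), 0L)
})

test_that("per-gene ANOVA agrees with the shared primitive and oneway.test", {
  set.seed(32)
  values <- matrix(rnorm(5 * 8, sd = 0.5), 5, 8,
                   dimnames = list(paste0("G", 1:5), NULL))
  values[1, 5:6] <- values[1, 5:6] - 3  # siPTBP1 effect
  nt <- toy_normalized_table(values)
  d <- differential_anova(nt)
  cond <- nt$design$condition
  for (g in 1:5) {
    groups <- split(values[g, ], cond)
    o <- one_way_anova(groups)
    expect_equal(d$f_stat[g], o$statistic, tolerance = 1e-10)
    expect_equal(d$p_anova[g], o$p_value, tolerance = 1e-10)
    ow <- oneway.test(values[g, ] ~ cond, var.equal = TRUE)
    expect_equal(d$f_stat[g], unname(ow$statistic), tolerance = 1e-10)
  }
  # contrasts are differences of condition means
  m <- tapply(values[1, ], cond, mean)
  expect_equal(d$fc_ptb[1], unname(m["siPTBP1"] - m["siNT"]))
  expect_equal(d$fc_rescue[1], unname(m["siPTBP1_siUPF1"] - m["siPTBP1"]))
  expect_equal(d$fc_upf1[1], unname(m["siUPF1"] - m["siNT"]))
})

test_that("degenerate genes follow the documented F conventions", {
  values <- rbind(G1 = rep(1, 8),
                  G2 = rep(c(0, 0, 5, 5), each = 2))
  nt <- toy_normalized_table(values)
  d <- differential_anova(nt)
  expect_equal(d$f_stat[1], 0)
  expect_equal(d$p_anova[1], 1)
  expect_equal(d$f_stat[2], Inf)
  expect_equal(d$p_anova[2], 0)
  expect_true(all(d$degenerate))
})

test_that("protection-set classification applies sign consistency and nests rescued in down", {
  # G1: clean protected pattern; G2: inconsistent replicate signs; G3: down, no rescue
  values <- rbind(
    G1 = c(5.0, 5.1, 5.0, 5.1, 4.0, 4.1, 5.0, 5.1),
    G2 = c(5.0, 5.1, 4.0, 6.1, 4.5, 5.6, 5.0, 5.1),
    G3 = c(5.0, 5.1, 5.0, 5.1, 4.0, 4.1, 4.0, 4.1))
  nt <- toy_normalized_table(values)
  d <- differential_anova(nt)
  sets <- classify_protection_sets(d, alpha = 0.05)
  expect_true("G1" %in% sets$down_genes)
  expect_true("G1" %in% sets$rescued_genes)
  expect_false("G2" %in% sets$down_genes)
  expect_true("G3" %in% sets$down_genes)
  expect_false("G3" %in% sets$rescued_genes)
  expect_true(all(sets$rescued_genes %in% sets$down_genes))
})

test_that("classification is monotone in alpha", {
  set.seed(33)
  values <- matrix(rnorm(50 * 8), 50, 8,
                   dimnames = list(paste0("G", 1:50), NULL))
  values[1:20, 5:6] <- values[1:20, 5:6] - 1.5
  d <- differential_anova(toy_normalized_table(values))
  alphas <- c(0.001, 0.01, 0.05, 0.2, 1)
  downs <- lapply(alphas, function(a) classify_protection_sets(d, a)$down_genes)
  for (i in seq_along(alphas)[-1]) {
    expect_true(all(downs[[i - 1]] %in% downs[[i]]))
  }
})

test_that("rescue correlation recovers monotone association and flags small strata", {
  d <- data.frame(gene_id = paste0("G", 1:10),
                  fc_ptb = -(1:10) / 5,
                  fc_rescue = (1:10) / 5,
                  fc_upf1 = 0)
  class(d) <- c("differential_result", class(d))
  r <- rescue_correlation(d, d$gene_id)
  expect_equal(r$overall$statistic, -1)
  expect_equal(r$fit$slope, -1, tolerance = 1e-10)
  strata <- setNames(c(rep(TRUE, 8), rep(FALSE, 2)), d$gene_id)
  r2 <- rescue_correlation(d, d$gene_id, strata)
  expect_equal(r2$hexamer_present$statistic, -1)
  expect_true(is.na(r2$hexamer_absent$statistic))
  expect_match(r2$hexamer_absent$note, "fewer than 3")
})

test_that("tied rescue correlations match the average-rank oracle", {
  set.seed(34)
  d <- data.frame(gene_id = paste0("G", 1:12),
                  fc_ptb = sample(c(-1, -2, -3), 12, replace = TRUE),
                  fc_rescue = sample(c(0.5, 1, 1.5), 12, replace = TRUE),
                  fc_upf1 = 0)
  class(d) <- c("differential_result", class(d))
  r <- rescue_correlation(d, d$gene_id)
  expect_equal(r$overall$statistic, oracle_spearman(d$fc_ptb, d$fc_rescue),
               tolerance = 1e-10)
})

test_that("3'UTR length CDFs report medians and K-S tests against the reference", {
  r <- utr_length_cdf(list(all = c(1, 2, 3), down = c(1, 2, 3)))
  expect_equal(unname(r$medians), c(2, 2))
  expect_equal(r$ks$D, 0)
  expect_equal(r$ks$p, 1)
  set.seed(35)
  x <- sample(100:2000, 7); y <- sample(100:2000, 6)
  r2 <- utr_length_cdf(list(all = x, down = y))
  o <- oracle_ks_exact(y, x)
  expect_equal(r2$ks$D, o$D, tolerance = 1e-10)
  expect_equal(r2$ks$p, o$p, tolerance = 1e-6)
})

test_that("planted protected genes are recovered far above chance end to end", {
  cfg <- simulation_config(seed = 7, n_genes = 1500)
  a <- simulate_annotation_and_sequences(cfg, sequences = FALSE)
  ct <- filter_low_counts(simulate_counts(cfg, a$labels), 25)
  utr_len <- setNames(a$labels$utr3_length, a$labels$gene_id)
  d <- differential_anova(normalize_counts(ct, utr_len))
  sets <- classify_protection_sets(d)
  truth <- a$labels$gene_id[a$labels$label == "protected"]
  rec <- recovery_metrics(sets$down_genes, truth, rownames(ct$counts))
  expect_gt(rec$sensitivity, 0.5)
  expect_lt(rec$fdr, 0.6)  # prevalence is 4%: calls are >10x enriched
  # direction checks: rescue positive, no planted siUPF1 effect on down set
  expect_gt(mean(d$fc_rescue[d$gene_id %in% sets$down_genes]), 0)
  expect_lt(abs(mean(d$fc_upf1[d$gene_id %in% sets$down_genes])), 0.3)
})
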