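small_cfg <- function(...) simulation_config(seed = 9, n_genes = 300, ...)

test_that("identical config and seed reproduce identical datasets", {
  d1 <- simulate_dataset(small_cfg())
  d2 <- simulate_dataset(small_cfg())
  expect_identical(d1$utr3_seq, d2$utr3_seq)
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$peaks, d2$peaks)
  expect_identical(d1$decay, d2$decay)
  expect_identical(d1$labels, d2$labels)
})

test_that("labels partition genes and geometry invariants hold", {
  a <- simulate_annotation_and_sequences(small_cfg())
  expect_true(all(a$labels$label %in% c("protected", "nmd_target", "background")))
  expect_equal(nrow(a$labels), 300)
  expect_equal(sum(a$labels$label == "protected"), 12)  # 4% of 300
  tt <- a$annotation$tx_table
  expect_equal(tt$utr3_length,
               a$labels$utr3_length[match(tt$transcript_id,
                                          a$labels$transcript_id)])
  # exemplar map is one transcript per gene
  expect_equal(length(a$annotation$exemplar_of), 300)
})

test_that("hexamers are planted on protected genes and nowhere near the TC otherwise", {
  a <- simulate_annotation_and_sequences(small_cfg())
  tab <- hexamer_presence_table(a$utr3_seq)
  lab <- a$labels$label[match(tab$transcript_id, a$labels$transcript_id)]
  decoy <- a$labels$decoy[match(tab$transcript_id, a$labels$transcript_id)]
  expect_true(all(tab$in_0_50[lab == "protected"]))
  expect_true(all(!tab$in_0_50[lab != "protected"]))
  expect_true(all(tab$in_50_100[decoy]))
  # non-decoy unprotected genes have no hexamer anywhere in [0, 400)
  clean <- lab != "protected" & !decoy
  expect_true(all(!tab$in_0_400[clean]))
})

test_that("a zero protected fraction plants no motifs", {
  a <- simulate_annotation_and_sequences(
    simulation_config(seed = 9, n_genes = 120, frac_protected = 0,
                      decoy_frac = 0))
  tab <- hexamer_presence_table(a$utr3_seq)
  expect_true(all(!tab$in_0_400))
})

test_that("protected genes draw longer 3'UTRs", {
  cfg <- simulation_config(seed = 42, n_genes = 5000)
  a <- simulate_annotation_and_sequences(cfg, sequences = FALSE)
  med <- tapply(a$labels$utr3_length, a$labels$label, median)
  expect_gt(med["protected"], med["background"])
})

test_that("counts encode the planted condition effects", {
  cfg <- simulation_config(seed = 10, n_genes = 2000)
  a <- simulate_annotation_and_sequences(cfg, sequences = FALSE)
  ct <- simulate_counts(cfg, a$labels)
  prot <- a$labels$label == "protected"
  nt_mean <- rowMeans(ct$counts[, ct$design$condition == "siNT"])
  ptb_mean <- rowMeans(ct$counts[, ct$design$condition == "siPTBP1"])
  ratio <- sum(ptb_mean[prot]) / sum(nt_mean[prot])
  expect_equal(ratio, 0.5, tolerance = 0.1)
  # full rescue back to baseline in the double knockdown
  dbl_mean <- rowMeans(ct$counts[, ct$design$condition == "siPTBP1_siUPF1"])
  expect_equal(sum(dbl_mean[prot]) / sum(nt_mean[prot]), 1, tolerance = 0.15)
  # zero dispersion reduces to Poisson-like counts
  cfg0 <- simulation_config(seed = 10, n_genes = 500, nb_dispersion = 0,
                            frac_protected = 0, frac_nmd_targets = 0)
  a0 <- simulate_annotation_and_sequences(cfg0, sequences = FALSE)
  ct0 <- simulate_counts(cfg0, a0$labels)
  mu <- rowMeans(ct0$counts)
  v <- apply(ct0$counts, 1, var)
  keep <- mu > 50
  expect_equal(median(v[keep] / mu[keep]), 1, tolerance = 0.25)
})

test_that("planted CLIP peaks center near TC+100 and survive the width filter", {
  cfg <- simulation_config(seed = 11, n_genes = 2000, frac_protected = 0.5,
                           background_peak_rate = 0)
  a <- simulate_annotation_and_sequences(cfg, sequences = FALSE)
  pk <- simulate_clip_peaks(cfg, a$labels, a$annotation)
  expect_gte(nrow(pk$truth), 1000)
  expect_equal(mean(pk$truth$center_offset), 100, tolerance = 0.05)
  expect_equal(nrow(filter_peaks_by_width(pk$peaks, 500)), nrow(pk$peaks))
  # zero background rate: every peak is on a protected gene
  annos <- annotate_peak_positions(pk$peaks, a$annotation)
  lab <- setNames(a$labels$label, a$labels$gene_id)
  expect_true(all(lab[annos$annotations$gene_id] == "protected"))
})

test_that("noiseless decay curves recover their half-lives exactly", {
  cfg <- simulation_config(seed = 12, noise_sigma_log = 0)
  dk <- simulate_decay(cfg)
  for (cs in unique(dk$timecourses$construct)) {
    f <- fit_exponential_decay(dk$timecourses[dk$timecourses$construct == cs, ])
    expect_equal(f$t_half, dk$truth$t_half[dk$truth$construct == cs],
                 tolerance = 1e-9)
  }
})

test_that("every generated artifact round-trips through its pipeline reader", {
  ds <- simulate_dataset(small_cfg())
  dir <- withr::local_tempdir()
  # annotation: GTF
  gtf <- file.path(dir, "ann.gtf")
  write_annotation_gtf(ds$annotation, gtf)
  ann2 <- load_annotation(gtf, dialect = "gtf")
  expect_setequal(names(ann2$transcripts), names(ds$annotation$transcripts))
  ids <- sample(names(ann2$transcripts), 10)
  for (id in ids) {
    expect_equal(ann2$transcripts[[id]]$utr3_length,
                 ds$annotation$transcripts[[id]]$utr3_length)
    expect_equal(ann2$transcripts[[id]]$cds_end_genomic,
                 ds$annotation$transcripts[[id]]$cds_end_genomic)
  }
  # sequences: FASTA
  fa <- file.path(dir, "utr3.fa")
  write_fasta(ds$utr3_seq, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(seqs), ds$utr3_seq)
  # peaks: BED
  bed <- file.path(dir, "peaks.bed")
  write_peaks_bed(ds$peaks, bed)
  pk2 <- read_peaks_bed(bed)
  expect_equal(pk2$start, ds$peaks$start)
  expect_equal(pk2$end, ds$peaks$end)
  expect_equal(pk2$strand, ds$peaks$strand)
  # counts + design: TSV
  cpath <- file.path(dir, "counts.tsv"); dpath <- file.path(dir, "design.tsv")
  write_count_table(ds$counts, cpath, dpath)
  ct2 <- read_count_table(cpath, dpath)
  expect_equal(ct2$counts, ds$counts$counts)
  expect_equal(ct2$design, ds$counts$design)
  # labels: TSV
  lpath <- file.path(dir, "labels.tsv")
  write_truth_labels(ds$labels, lpath)
  expect_equal(read_truth_labels(lpath), ds$labels)
})
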