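fastq_df <- function(seqs) {
  data.frame(id = sprintf("r%d", seq_along(seqs)), seq = seqs,
             qual = vapply(nchar(seqs), function(n)
               paste(rep("I", n), collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

test_that("FASTQ IO round-trips sequences and qualities", {
  reads <- fastq_df(c("GTTACGTACGT", "ACGTACGTACG"))
  reads$qual[1] <- "IIIIIIIHHGG"
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(back, reads)
  writeLines(c("@x", "ACGT", "+"), path)
  expect_error(read_fastq(path), "multiple of 4")
})

test_that("iCLIP preprocessing filters, collapses and trims in order", {
  reads <- fastq_df(c(
    "GTTAACGTCAGGT",   # kept
    "ACGTACGTAAGGT",   # no GTT prefix
    "GTTAACGTCAGGT",   # duplicate of first
    "GTTCCCCAAAT",     # kept -> AAAT after trim
    "GTTCCCC"))        # too short (7 nt)
  out <- preprocess_iclip(reads)
  expect_equal(out$reads$seq, c("TCAGGT", "AAAT"))
  expect_equal(nchar(out$reads$qual), nchar(out$reads$seq))
  # conservation at every step
  expect_true(all(out$log$n_in == out$log$n_kept + out$log$n_dropped))
  expect_equal(out$log$n_dropped[out$log$step == "gtt_prefix_filter"], 1L)
  expect_equal(out$log$n_dropped[out$log$step == "min_length_8"], 1L)
  expect_equal(out$log$n_dropped[out$log$step == "collapse_duplicates"], 1L)
})

test_that("HITS-CLIP preprocessing collapses (case-insensitively) and trims 3 nt", {
  reads <- fastq_df(c("ACGTTTT", "acgtttt", "ACGTTTTTT", "ACG"))
  out <- preprocess_hitsclip(reads)
  expect_equal(out$reads$seq, c("TTTT", "TTTTTT"))
  expect_equal(out$log$n_dropped[out$log$step == "min_length_4"], 1L)
  expect_equal(out$log$n_dropped[out$log$step == "collapse_duplicates"], 1L)
  expect_true(all(out$log$n_in == out$log$n_kept + out$log$n_dropped))
})

test_that("peak width filter is strictly 'narrower than'", {
  pk <- clip_peaks("chr1", c(0, 0, 0), c(499, 500, 501), c("+", "+", "+"))
  kept <- filter_peaks_by_width(pk, 500)
  expect_equal(kept$end - kept$start, 499)
  expect_equal(nrow(filter_peaks_by_width(pk[0, ], 500)), 0L)
})

peak_test_annotation <- function() {
  # two well-separated genes plus an overlapping pair on chr2
  t1 <- transcript_model("T1", "G1", "chr1", "+", rbind(c(0, 2000)), c(100, 400))
  t2 <- transcript_model("T2", "G2", "chr1", "-", rbind(c(5000, 7000)),
                         c(6600, 6900))
  t3 <- transcript_model("T3", "G3", "chr2", "+", rbind(c(0, 1500)), c(100, 400))
  t4 <- transcript_model("T4", "G4", "chr2", "+", rbind(c(1000, 2500)),
                         c(1100, 2100))  # utr3 400 nt, below the length cutoff
  select_exemplars(genome_annotation(list(t1, t2, t3, t4)))
}

test_that("peak centers map to TC-relative offsets with strand symmetry", {
  ann <- peak_test_annotation()
  # + strand: TC origin at 400, center floor((490+510)/2) = 500 -> offset 100
  pk <- clip_peaks("chr1", 490, 510, "+")
  r <- annotate_peak_positions(pk, ann)
  expect_equal(r$annotations$center, 500)
  expect_equal(r$annotations$center_offset, 100)
  expect_equal(r$annotations$gene_id, "G1")
  # - strand mirror: origin at 6599 read downstream toward lower coordinates
  pk2 <- clip_peaks("chr1", 6489, 6509, "-")
  r2 <- annotate_peak_positions(pk2, ann)
  expect_equal(r2$annotations$center_offset, 100)
  # strand mismatch -> unassigned
  pk3 <- clip_peaks("chr1", 490, 510, "-")
  r3 <- annotate_peak_positions(pk3, ann)
  expect_equal(nrow(r3$annotations), 0L)
  expect_equal(r3$n_unassigned, 1L)
  # center inside two exemplar spans -> ambiguous, assigned to neither
  pk4 <- clip_peaks("chr2", 1190, 1210, "+")
  r4 <- annotate_peak_positions(pk4, ann)
  expect_equal(nrow(r4$annotations), 0L)
  expect_equal(r4$n_ambiguous, 1L)
})

test_that("density profiles count centers into uniform bins and conserve totals", {
  annos <- data.frame(gene_id = "G1", transcript_id = "T1",
                      center_offset = c(10, 15, 30), weight = c(2, 3, 4))
  p <- tc_density_profile(annos, window = c(0, 40), bin = 20)
  expect_equal(p$value, c(2, 1))
  expect_equal(sum(p$value), nrow(annos))
  pr <- tc_density_profile(annos, window = c(0, 40), bin = 20,
                           weight_mode = "reads")
  expect_equal(pr$value, c(5, 4))
  p0 <- tc_density_profile(annos[0, ], window = c(0, 40), bin = 20)
  expect_true(all(p0$value == 0))
  expect_error(tc_density_profile(annos, window = c(0, 50), bin = 20),
               "multiples")
})

test_that("density profiles are invariant under genome-wide translation", {
  ann <- peak_test_annotation()
  pk <- clip_peaks("chr1", c(420, 480, 700), c(460, 540, 760),
                   c("+", "+", "+"))
  p1 <- tc_density_profile(annotate_peak_positions(pk, ann)$annotations,
                           c(-100, 500), 20)
  shift <- 10000
  t1s <- transcript_model("T1", "G1", "chr1", "+",
                          rbind(c(0, 2000) + shift), c(100, 400) + shift)
  anns <- select_exemplars(genome_annotation(list(t1s)))
  pks <- clip_peaks("chr1", pk$start + shift, pk$end + shift, pk$strand)
  p2 <- tc_density_profile(annotate_peak_positions(pks, anns)$annotations,
                           c(-100, 500), 20)
  expect_equal(p1$value, p2$value)
})

test_that("positional classes respect interval edges and the 3'UTR length cutoff", {
  # G1 utr3 1600 nt, G2 utr3 1600? compute: t2 utr3 = [5000,6600) -> 1600
  ann <- peak_test_annotation()
  annos <- data.frame(
    gene_id = c("G1", "G1", "G2"), transcript_id = c("T1", "T1", "T2"),
    center_offset = c(150, 650, 350), weight = 1)
  cls <- classify_by_peak_interval(annos, ann)
  g1 <- cls[cls$gene_id == "G1", ]
  expect_true(g1$peak_0_200)
  expect_false(g1$peak_200_500)
  expect_false(g1$no_proximal)
  g2 <- cls[cls$gene_id == "G2", ]
  expect_true(g2$peak_200_500)
  expect_true(!g2$peak_0_200 && !g2$no_proximal)
  # genes with short 3'UTRs are excluded from the comparison
  expect_false("G4" %in% cls$gene_id)  # utr3 = 1000? check below
  tt <- exemplar_table(ann)
  expect_true(all(cls$utr3_length > 500))
})

test_that("NMD-sensitivity CDF restricts to the inter-quartile band and flags tiny classes", {
  set.seed(41)
  genes <- paste0("G", 1:400)
  utr <- setNames(exp(rnorm(400, log(1200), 0.6)), genes)
  fc <- setNames(rnorm(400, 0.5, 0.3), genes)
  shielded <- genes[1:80]
  fc[shielded] <- rnorm(80, 0, 0.3)
  classes <- list(prox = shielded, tiny = genes[1:2],
                  none = genes[81:400])
  r <- nmd_sensitivity_cdf(classes, fc, utr, reference = "none")
  expect_equal(r$band, percentile(utr, c(0.25, 0.75)))
  expect_lt(r$ks[r$ks$class == "prox", "p"], 0.05)
  expect_true(is.na(r$ks[r$ks$class == "tiny", "p"]))
  # identical class equals reference -> D = 0, p = 1
  r2 <- nmd_sensitivity_cdf(list(a = genes, none = genes), fc, utr,
                            reference = "none")
  expect_equal(r2$ks$D, 0)
  expect_equal(r2$ks$p, 1)
  # band filter matches the percentile oracle
  expect_equal(r$band, unname(c(oracle_percentile(utr, 0.25),
                                oracle_percentile(utr, 0.75))))
})

test_that("BED peak IO round-trips coordinates, strand and weight", {
  pk <- clip_peaks(c("chr1", "chr2"), c(100, 250), c(180, 400),
                   c("+", "-"), weight = c(7, 9))
  path <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(pk, path)
  back <- read_peaks_bed(path)
  expect_equal(back$chrom, pk$chrom)
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$strand, pk$strand)
  expect_equal(back$weight, pk$weight)
})
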