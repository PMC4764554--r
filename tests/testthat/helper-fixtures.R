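# Hand-built transcripts exercising strand and intron geometry.

tx_plus_single <- function() {
  transcript_model("NM_P1", "GENEP", "chr1", "+",
                   rbind(c(0, 1000)), c(100, 400))
}

tx_minus_single <- function() {
  transcript_model("NM_M1", "GENEM", "chr1", "-",
                   rbind(c(0, 1000)), c(600, 900))
}

# intron inside the 3'UTR: exons [0,500) + [700,1200), CDS ends at 450
tx_plus_utr_intron <- function() {
  transcript_model("NM_P2", "GENEI", "chr1", "+",
                   rbind(c(0, 500), c(700, 1200)), c(100, 450))
}

tx_minus_utr_intron <- function() {
  transcript_model("NM_M2", "GENEJ", "chr1", "-",
                   rbind(c(0, 500), c(700, 1200)), c(750, 1100))
}

fixture_transcripts <- function() {
  list(tx_plus_single(), tx_minus_single(), tx_plus_utr_intron(),
       tx_minus_utr_intron())
}

# a genome whose chr1 is long enough for the fixtures
fixture_genome <- function(seed = 7) {
  set.seed(seed)
  c(chr1 = paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                 collapse = ""))
}

# small four-condition count table with planted patterns
toy_count_table <- function(counts) {
  samples <- as.vector(t(outer(c("siNT", "siUPF1", "siPTBP1",
                                 "siPTBP1_siUPF1"), 1:3, paste, sep = "_")))
  colnames(counts) <- samples
  design <- data.frame(sample = samples,
                       condition = sub("_[0-9]+$", "", samples),
                       replicate = as.integer(sub("^.*_", "", samples)))
  count_table(counts, design)
}

toy_normalized_table <- function(values) {
  samples <- as.vector(t(outer(c("siNT", "siUPF1", "siPTBP1",
                                 "siPTBP1_siUPF1"), 1:2, paste, sep = "_")))
  colnames(values) <- samples
  design <- data.frame(sample = samples,
                       condition = sub("_[0-9]+$", "", samples),
                       replicate = as.integer(sub("^.*_", "", samples)))
  normalized_table(values, design)
}
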