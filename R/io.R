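#' @title Dataset IO
#' @description Writers and readers for the pipeline's exchange formats:
#'   GTF and refFlat annotation, FASTA sequences, count-matrix and design
#'   TSVs, truth-label TSVs, and the JSON summary report. Every artifact
#'   the synthetic generator writes is readable by the corresponding
#'   pipeline reader.
#' @name io
NULL

#' Write an annotation as GTF
#'
#' Emits `exon` and `CDS` features per transcript (the CDS extent includes
#' the stop codon, matching what [load_annotation()] expects).
#'
#' @param ann a [genome_annotation].
#' @param path output GTF file.
#' @export
write_annotation_gtf <- function(ann, path) {
  rows <- lapply(ann$transcripts, function(t) {
    ex <- data.frame(start = t$exons[, 1], end = t$exons[, 2], type = "exon")
    cds_iv <- .clip_intervals(t$exons, t$cds[1], t$cds[2])
    cds <- data.frame(start = cds_iv[, 1], end = cds_iv[, 2], type = "CDS")
    out <- rbind(ex, cds)
    out$chrom <- t$chrom
    out$strand <- t$strand
    out$transcript_id <- t$transcript_id
    out$gene_id <- t$gene_id
    out
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1L, df$end), strand = df$strand,
    type = df$type, gene_id = df$gene_id, transcript_id = df$transcript_id,
    source = "nmdprotect")
  # CDS phase is irrelevant here (only the CDS extent is read back)
  suppressWarnings(rtracklayer::export(gr, path, format = "gtf"))
  invisible(path)
}

#' Write an annotation as refFlat
#'
#' @param ann a [genome_annotation].
#' @param path output file (tab-delimited, UCSC refFlat columns).
#' @export
write_annotation_refflat <- function(ann, path) {
  lines <- vapply(ann$transcripts, function(t) {
    paste(t$gene_id, t$transcript_id, t$chrom, t$strand,
          t$exons[1, 1], t$exons[nrow(t$exons), 2],
          t$cds[1], t$cds[2], nrow(t$exons),
          paste0(paste(t$exons[, 1], collapse = ","), ","),
          paste0(paste(t$exons[, 2], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output FASTA file.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write count matrix and design TSVs
#'
#' @param ct a [count_table].
#' @param counts_path genes x samples TSV (header row = sample ids, first
#'   column `gene_id`).
#' @param design_path TSV with columns sample, condition, replicate.
#' @export
write_count_table <- function(ct, counts_path, design_path) {
  df <- data.frame(gene_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ct$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Read count matrix and design TSVs
#'
#' @param counts_path,design_path files written by [write_count_table()].
#' @return A [count_table].
#' @export
read_count_table <- function(counts_path, design_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  count_table(counts, design)
}

#' Write truth labels as TSV
#'
#' @param labels label data frame from the synthetic generator.
#' @param path output file.
#' @export
write_truth_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read truth labels
#'
#' @param path TSV written by [write_truth_labels()].
#' @return Data frame.
#' @export
read_truth_labels <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write the JSON summary report
#'
#' @param report named list of summary values.
#' @param path output JSON file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
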