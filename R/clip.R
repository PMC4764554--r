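#' @title CLIP read preprocessing and TC-anchored peak analysis
#' @description Applies the protocol-specific read-cleanup rules (iCLIP:
#'   GTT-prefix filter, duplicate collapsing, 7-nt barcode trim; HITS-CLIP:
#'   duplicate collapsing, 3-nt trim), filters called peaks by width,
#'   assigns peak centers to exemplar transcripts, and computes
#'   termination-codon-anchored density profiles and positional gene
#'   classes. Peak calling itself is upstream and out of scope; peaks are
#'   consumed as BED.
#' @name clip
NULL

#' Read a FASTQ file
#'
#' Minimal 4-line-record reader; qualities are kept alongside sequences so
#' they survive trimming.
#'
#' @param path FASTQ file (uncompressed).
#' @return Data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("FASTQ record count not a multiple of 4: ", path)
  ix <- seq(1L, length(lines), by = 4L)
  ids <- sub("^@", "", lines[ix])
  seqs <- lines[ix + 1L]
  quals <- lines[ix + 3L]
  if (any(nchar(seqs) != nchar(quals))) {
    stop("sequence/quality length mismatch in ", path)
  }
  data.frame(id = ids, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param reads data frame with `id`, `seq`, `qual`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), 4L)] <- reads$seq
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

.log_step <- function(log, step, n_in, n_kept) {
  rbind(log, data.frame(step = step, n_in = n_in, n_kept = n_kept,
                        n_dropped = n_in - n_kept, stringsAsFactors = FALSE))
}

#' Preprocess iCLIP reads
#'
#' Order of operations: (1) remove reads not starting with `GTT` (the
#' reverse-transcription primer prefix); (2) drop reads shorter than 8 nt;
#' (3) collapse exact sequence duplicates (identical degenerate barcodes);
#' (4) trim the first 7 nt (barcode) from sequence and quality. Sequences
#' are case-normalized before collapsing; read counts at every step are
#' logged and conserved (kept + dropped = in).
#'
#' @param reads data frame from [read_fastq()].
#' @return List with `reads` (processed data frame) and `log` (per-step
#'   counts).
#' @export
preprocess_iclip <- function(reads) {
  log <- NULL
  reads$seq <- toupper(reads$seq)
  n0 <- nrow(reads)
  keep <- startsWith(reads$seq, "GTT")
  reads <- reads[keep, , drop = FALSE]
  log <- .log_step(log, "gtt_prefix_filter", n0, nrow(reads))

  n1 <- nrow(reads)
  reads <- reads[nchar(reads$seq) >= 8L, , drop = FALSE]
  log <- .log_step(log, "min_length_8", n1, nrow(reads))

  n2 <- nrow(reads)
  reads <- reads[!duplicated(reads$seq), , drop = FALSE]
  log <- .log_step(log, "collapse_duplicates", n2, nrow(reads))

  n3 <- nrow(reads)
  reads$seq <- substring(reads$seq, 8L)
  reads$qual <- substring(reads$qual, 8L)
  log <- .log_step(log, "trim_first_7", n3, nrow(reads))
  rownames(reads) <- NULL
  list(reads = reads, log = log)
}

#' Preprocess HITS-CLIP reads
#'
#' Collapse exact sequence duplicates (after case normalization), then
#' trim the first 3 nt; reads shorter than 4 nt are dropped with a count.
#'
#' @param reads data frame from [read_fastq()].
#' @return List with `reads` and `log` as in [preprocess_iclip()].
#' @export
preprocess_hitsclip <- function(reads) {
  log <- NULL
  reads$seq <- toupper(reads$seq)
  n0 <- nrow(reads)
  reads <- reads[nchar(reads$seq) >= 4L, , drop = FALSE]
  log <- .log_step(log, "min_length_4", n0, nrow(reads))

  n1 <- nrow(reads)
  reads <- reads[!duplicated(reads$seq), , drop = FALSE]
  log <- .log_step(log, "collapse_duplicates", n1, nrow(reads))

  n2 <- nrow(reads)
  reads$seq <- substring(reads$seq, 4L)
  reads$qual <- substring(reads$qual, 4L)
  log <- .log_step(log, "trim_first_3", n2, nrow(reads))
  rownames(reads) <- NULL
  list(reads = reads, log = log)
}

#' Construct a CLIP peak table
#'
#' @param chrom,start,end,strand peak coordinates, 0-based half-open.
#' @param weight optional supporting read count per peak.
#' @return Data frame of class `clip_peaks`.
#' @export
clip_peaks <- function(chrom, start, end, strand, weight = NA_real_) {
  if (any(end <= start)) stop("peaks must satisfy end > start")
  if (any(!strand %in% c("+", "-"))) stop("peak strand must be '+' or '-'")
  out <- data.frame(chrom = chrom, start = as.numeric(start),
                    end = as.numeric(end), strand = strand,
                    weight = as.numeric(weight), stringsAsFactors = FALSE)
  class(out) <- c("clip_peaks", class(out))
  out
}

#' Read CLIP peaks from BED
#'
#' BED6; the score column, when present, is carried as the peak weight.
#'
#' @param path BED file.
#' @return A `clip_peaks` data frame (0-based half-open coordinates).
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  w <- if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_
  clip_peaks(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L,
             GenomicRanges::end(gr),
             as.character(GenomicRanges::strand(gr)),
             weight = w)
}

#' Write CLIP peaks as BED
#'
#' @param peaks a `clip_peaks` data frame.
#' @param path output BED file.
#' @export
write_peaks_bed <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = peaks$strand)
  gr$name <- sprintf("peak_%05d", seq_along(gr))
  gr$score <- ifelse(is.na(peaks$weight), 0, peaks$weight)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Filter peaks by width
#'
#' Retains peaks strictly narrower than `max_width` (width = end - start).
#'
#' @param peaks a `clip_peaks` data frame.
#' @param max_width width bound in nt (default 500; "narrower than" is
#'   strict).
#' @return Filtered peaks.
#' @export
filter_peaks_by_width <- function(peaks, max_width = 500) {
  peaks[(peaks$end - peaks$start) < max_width, , drop = FALSE]
}

#' Assign peak centers to exemplar transcripts
#'
#' The peak center is `floor((start + end) / 2)`. A center is assigned to
#' the unique exemplar transcript whose span contains it on the matching
#' strand; centers matching no exemplar are unassigned, centers matching
#' more than one are ambiguous, and both are counted rather than assigned.
#' The TC-relative offset of the center is computed in the requested
#' distance mode (default genomic, matching chromosomal CLIP coordinates;
#' in spliced mode intronic centers become unassigned).
#'
#' @param peaks a `clip_peaks` data frame.
#' @param ann a [genome_annotation] with exemplars selected.
#' @param mode `"genomic"` (default) or `"spliced"`.
#' @return List with `annotations` (data frame: peak coordinates,
#'   `transcript_id`, `gene_id`, `center`, `center_offset`),
#'   `n_unassigned`, and `n_ambiguous`.
#' @export
annotate_peak_positions <- function(peaks, ann, mode = c("genomic", "spliced")) {
  mode <- match.arg(mode)
  if (length(ann$exemplar_of) == 0L) stop("exemplars not selected")
  ex <- exemplar_table(ann)
  center <- floor((peaks$start + peaks$end) / 2)
  q <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(center + 1L, center + 1L),
                              strand = peaks$strand)
  s <- GenomicRanges::GRanges(ex$chrom,
                              IRanges::IRanges(ex$span_start + 1L, ex$span_end),
                              strand = ex$strand)
  ov <- GenomicRanges::findOverlaps(q, s, ignore.strand = FALSE)
  nhit <- tabulate(S4Vectors::queryHits(ov), nbins = nrow(peaks))
  n_ambiguous <- sum(nhit > 1L)
  uniq <- which(nhit == 1L)
  hit_tx <- rep(NA_integer_, nrow(peaks))
  one <- S4Vectors::queryHits(ov) %in% uniq
  hit_tx[S4Vectors::queryHits(ov)[one]] <- S4Vectors::subjectHits(ov)[one]

  n_unassigned <- sum(nhit == 0L)
  tx_ids <- ex$transcript_id[hit_tx[uniq]]
  if (mode == "genomic") {
    cds_end <- vapply(ann$transcripts[tx_ids], `[[`, numeric(1),
                      "cds_end_genomic")
    str <- ex$strand[hit_tx[uniq]]
    off <- ifelse(str == "+", center[uniq] - (cds_end + 1),
                  (cds_end - 1) - center[uniq])
  } else {
    off <- vapply(seq_along(uniq), function(j) {
      tryCatch(tc_relative_position(ann$transcripts[[tx_ids[j]]],
                                    center[uniq[j]], mode = "spliced"),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  ok <- !is.na(off)
  n_unassigned <- n_unassigned + sum(!ok)  # intronic in spliced mode
  iu <- uniq[ok]
  annotations <- data.frame(
    chrom = peaks$chrom[iu], start = peaks$start[iu], end = peaks$end[iu],
    strand = peaks$strand[iu], weight = peaks$weight[iu],
    transcript_id = tx_ids[ok], gene_id = ex$gene_id[hit_tx[iu]],
    center = center[iu], center_offset = unname(off[ok]),
    stringsAsFactors = FALSE)
  list(annotations = annotations, n_unassigned = n_unassigned,
       n_ambiguous = n_ambiguous)
}

#' TC-anchored density profile
#'
#' Bins peak-center offsets into uniform bins (default 20 nt) across a
#' TC-relative window, summing 1 per annotation (`"peaks"` mode) or the
#' peak weight (`"reads"` mode) in the bin containing each center;
#' aggregation is a raw sum across all exemplar transcripts (set
#' `per_transcript = TRUE` to average per transcript instead).
#'
#' @param annos annotation data frame from [annotate_peak_positions()].
#' @param window length-2 TC-relative range; endpoints must be multiples
#'   of `bin`.
#' @param bin bin width in nt (default 20).
#' @param weight_mode `"peaks"` or `"reads"`.
#' @param per_transcript normalize each transcript's contribution to 1.
#' @return Object of class `density_profile`: data frame with `bin_start`,
#'   `bin_end`, `value`.
#' @export
tc_density_profile <- function(annos, window = c(-400, 1000), bin = 20,
                               weight_mode = c("peaks", "reads"),
                               per_transcript = FALSE) {
  weight_mode <- match.arg(weight_mode)
  if (any(window %% bin != 0)) stop("window endpoints must be multiples of bin")
  edges <- seq(window[1], window[2], by = bin)
  nb <- length(edges) - 1L
  values <- numeric(nb)
  inw <- annos$center_offset >= window[1] & annos$center_offset < window[2]
  a <- annos[inw, , drop = FALSE]
  if (nrow(a)) {
    idx <- floor((a$center_offset - window[1]) / bin) + 1L
    w <- if (weight_mode == "reads") {
      if (anyNA(a$weight)) stop("reads mode requires peak weights")
      a$weight
    } else rep(1, nrow(a))
    if (per_transcript) {
      tot <- tapply(w, a$transcript_id, sum)
      w <- w / as.numeric(tot[a$transcript_id])
    }
    agg <- tapply(w, factor(idx, levels = seq_len(nb)), sum)
    values <- as.numeric(ifelse(is.na(agg), 0, agg))
  }
  out <- data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
                    value = values)
  attr(out, "weight_mode") <- weight_mode
  class(out) <- c("density_profile", class(out))
  out
}

#' Classify genes by TC-relative peak position
#'
#' Over exemplar genes with 3'UTRs longer than `min_utr3` (strict, to
#' avoid length bias), flags whether each gene has a peak centered in each
#' interval (default \[0, 200) and \[200, 500); not mutually exclusive) and
#' whether it lacks any TC-proximal peak (no center in the union of the
#' intervals).
#'
#' @param annos annotation data frame from [annotate_peak_positions()].
#' @param ann a [genome_annotation] with exemplars selected.
#' @param intervals list of `c(a, b)` TC-relative intervals, half-open.
#' @param min_utr3 minimum exemplar 3'UTR length (nt), exclusive.
#' @return Data frame: `gene_id`, `utr3_length`, one logical
#'   `peak_<a>_<b>` column per interval, and `no_proximal`.
#' @export
classify_by_peak_interval <- function(annos, ann,
                                      intervals = list(c(0, 200), c(200, 500)),
                                      min_utr3 = 500) {
  ex <- exemplar_table(ann)
  ex <- ex[ex$utr3_length > min_utr3, , drop = FALSE]
  out <- data.frame(gene_id = ex$gene_id, utr3_length = ex$utr3_length,
                    stringsAsFactors = FALSE)
  lo <- min(vapply(intervals, `[`, numeric(1), 1))
  hi <- max(vapply(intervals, `[`, numeric(1), 2))
  for (iv in intervals) {
    g <- unique(annos$gene_id[annos$center_offset >= iv[1] &
                                annos$center_offset < iv[2]])
    out[[sprintf("peak_%d_%d", iv[1], iv[2])]] <- out$gene_id %in% g
  }
  prox <- unique(annos$gene_id[annos$center_offset >= lo &
                                 annos$center_offset < hi])
  out$no_proximal <- !(out$gene_id %in% prox)
  out
}

#' NMD-sensitivity ECDF comparison across gene classes
#'
#' Restricts genes to a 3'UTR-length band (by default the inter-quartile
#' band recomputed from the supplied lengths, not a hard-coded range) and
#' compares each class's distribution of siUPF1 log2 fold changes to the
#' reference class by two-tailed Kolmogorov-Smirnov test. Classes with
#' fewer than 3 genes in the band are flagged and get no p-value.
#'
#' @param classes named list of gene-id vectors; one name must be the
#'   `reference`.
#' @param fc_upf1 named numeric vector of siUPF1 vs siNT log2 fold
#'   changes.
#' @param utr3_length named numeric vector of exemplar 3'UTR lengths for
#'   the gene universe.
#' @param band optional `c(lo, hi)` length band; `NULL` computes the
#'   25th-75th percentile band from `utr3_length`.
#' @param reference name of the reference class.
#' @return List with `band`, `ecdf` (per class), and `ks` (data frame:
#'   class, n, D, p).
#' @export
nmd_sensitivity_cdf <- function(classes, fc_upf1, utr3_length, band = NULL,
                                reference = "no_proximal") {
  stopifnot(reference %in% names(classes))
  if (is.null(band)) {
    band <- percentile(utr3_length, c(0.25, 0.75))
  }
  in_band <- names(utr3_length)[utr3_length >= band[1] & utr3_length <= band[2]]
  vals <- lapply(classes, function(g) {
    g <- intersect(intersect(g, in_band), names(fc_upf1))
    fc_upf1[g]
  })
  ref <- vals[[reference]]
  if (length(ref) < 3L) stop("reference class has fewer than 3 genes in band")
  ks <- do.call(rbind, lapply(setdiff(names(vals), reference), function(nm) {
    v <- vals[[nm]]
    if (length(v) < 3L) {
      data.frame(class = nm, n = length(v), D = NA_real_, p = NA_real_,
                 note = "fewer than 3 genes", stringsAsFactors = FALSE)
    } else {
      r <- ks_two_sample(v, ref)
      data.frame(class = nm, n = length(v), D = r$statistic, p = r$p_value,
                 note = "", stringsAsFactors = FALSE)
    }
  }))
  list(band = band, ecdf = lapply(vals, function(v)
    if (length(v)) stats::ecdf(v) else NULL),
    values = vals, ks = ks, reference = reference)
}
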