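#' @title Transcript annotation and termination-codon-relative coordinates
#' @description All genomic intervals are 0-based half-open internally (BED
#'   convention); 1-based dialects (GTF) are converted at the IO boundary.
#'   The coordinate origin for every positional analysis is the first
#'   nucleotide 3' of the stop codon (offset 0); "within N nt of the TC"
#'   means offsets in \[0, N).
#' @name annotations
NULL

.validate_exons <- function(exons) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) stop("exon with non-positive width")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop("overlapping exons")
  }
  exons
}

#' Build a transcript model
#'
#' Represents one coding transcript: exon structure, CDS extent (which must
#' include the stop codon), and the derived 3'UTR geometry. The genomic
#' coordinate of the last base of the stop codon (`cds_end_genomic`) anchors
#' all TC-relative offsets.
#'
#' @param transcript_id,gene_id accession strings.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of 0-based half-open `[start, end)`
#'   genomic intervals; sorted and non-overlapping after construction.
#' @param cds length-2 vector `c(lo, hi)`: the genomic CDS extent, 0-based
#'   half-open, stop codon included.
#' @return An object of class `transcript_model` with fields
#'   `cds_end_genomic`, `utr3_intervals`, and `utr3_length` derived.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons, cds) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- .validate_exons(exons)
  cds <- as.numeric(cds)
  if (length(cds) != 2L || cds[2] <= cds[1]) stop("cds must be c(lo, hi), hi > lo")
  cds_end <- if (strand == "+") cds[2] - 1 else cds[1]
  if (!any(exons[, 1] <= cds_end & cds_end < exons[, 2])) {
    stop(sprintf("transcript %s: CDS end outside exons", transcript_id))
  }
  # 3'UTR = exonic positions strictly 3' of the stop codon
  utr3 <- if (strand == "+") {
    .clip_intervals(exons, cds_end + 1, Inf)
  } else {
    .clip_intervals(exons, -Inf, cds_end)
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, cds = cds,
         cds_end_genomic = cds_end, utr3_intervals = utr3,
         utr3_length = if (nrow(utr3)) sum(utr3[, 2] - utr3[, 1]) else 0),
    class = "transcript_model"
  )
}

# intersect sorted intervals with [lo, hi)
.clip_intervals <- function(iv, lo, hi) {
  s <- pmax(iv[, 1], lo)
  e <- pmin(iv[, 2], hi)
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s:%s %d exon(s), 3'UTR %d nt>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$utr3_length))
  invisible(x)
}

#' Assemble a genome annotation
#'
#' @param transcripts list of [transcript_model] objects.
#' @param n_noncoding count of non-coding records excluded upstream.
#' @param n_skipped count of records skipped for malformed geometry.
#' @return An object of class `genome_annotation`: the transcripts (named by
#'   transcript id), an `exemplar_of` map (empty until
#'   [select_exemplars()]), and a `tx_table` summary data frame.
#' @export
genome_annotation <- function(transcripts, n_noncoding = 0L, n_skipped = 0L) {
  ids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript ids")
  names(transcripts) <- ids
  tx_table <- data.frame(
    transcript_id = ids,
    gene_id = vapply(transcripts, `[[`, character(1), "gene_id"),
    chrom = vapply(transcripts, `[[`, character(1), "chrom"),
    strand = vapply(transcripts, `[[`, character(1), "strand"),
    span_start = vapply(transcripts, function(t) t$exons[1, 1], numeric(1)),
    span_end = vapply(transcripts, function(t) t$exons[nrow(t$exons), 2], numeric(1)),
    utr3_length = vapply(transcripts, `[[`, numeric(1), "utr3_length"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(transcripts = transcripts, exemplar_of = character(0),
         tx_table = tx_table, n_noncoding = n_noncoding, n_skipped = n_skipped),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(paste0("<genome_annotation: %d transcripts, %d genes, ",
                     "%d exemplars selected (%d non-coding excluded)>\n"),
              length(x$transcripts), length(unique(x$tx_table$gene_id)),
              length(x$exemplar_of), x$n_noncoding))
  invisible(x)
}

#' Load a transcript annotation
#'
#' Reads coding transcripts from a GTF file or a refFlat-style table and
#' derives 3'UTR geometry. Non-coding transcripts are excluded and counted;
#' a transcript whose CDS end falls outside its exons is skipped with a
#' warning. GTF coordinates (1-based inclusive) are converted to the
#' internal 0-based half-open convention on read; refFlat is already
#' 0-based half-open. In GTF input the CDS extent is the union of `CDS` and
#' any `stop_codon` features, so the stop codon is always included.
#'
#' @param path annotation file.
#' @param dialect `"gtf"` or `"refflat"`.
#' @return A [genome_annotation].
#' @export
load_annotation <- function(path, dialect = c("gtf", "refflat")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  recs <- if (dialect == "refflat") .parse_refflat(path) else .parse_gtf(path)
  transcripts <- list()
  n_skipped <- 0L
  for (r in recs$records) {
    t <- tryCatch(
      transcript_model(r$transcript_id, r$gene_id, r$chrom, r$strand,
                       r$exons, r$cds),
      error = function(e) {
        warning(sprintf("skipping transcript %s: %s",
                        r$transcript_id, conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(t)) transcripts[[t$transcript_id]] <- t else n_skipped <- n_skipped + 1L
  }
  if (recs$n_noncoding > 0L) {
    message(sprintf("load_annotation: excluded %d non-coding transcript(s)",
                    recs$n_noncoding))
  }
  genome_annotation(transcripts, n_noncoding = recs$n_noncoding,
                    n_skipped = n_skipped)
}

# refFlat: geneName name chrom strand txStart txEnd cdsStart cdsEnd
#          exonCount exonStarts exonEnds (0-based half-open, UCSC)
.parse_refflat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  records <- list()
  n_noncoding <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) {
      stop(sprintf("malformed refFlat record at line %d of %s", i, path))
    }
    cds_lo <- suppressWarnings(as.numeric(f[7]))
    cds_hi <- suppressWarnings(as.numeric(f[8]))
    if (is.na(cds_lo) || is.na(cds_hi)) {
      stop(sprintf("malformed refFlat record at line %d of %s", i, path))
    }
    if (cds_lo == cds_hi) { # non-coding
      n_noncoding <- n_noncoding + 1L
      next
    }
    starts <- as.numeric(strsplit(f[10], ",", fixed = TRUE)[[1]])
    ends <- as.numeric(strsplit(f[11], ",", fixed = TRUE)[[1]])
    if (anyNA(starts) || anyNA(ends) || length(starts) != length(ends)) {
      stop(sprintf("malformed refFlat record at line %d of %s", i, path))
    }
    records[[length(records) + 1L]] <- list(
      gene_id = f[1], transcript_id = f[2], chrom = f[3], strand = f[4],
      exons = cbind(starts, ends), cds = c(cds_lo, cds_hi))
  }
  list(records = records, n_noncoding = n_noncoding)
}

.parse_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) {
                   stop(sprintf("malformed GTF %s: %s", path,
                                conditionMessage(e)), call. = FALSE)
                 })
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (!all(c("type", "transcript_id", "gene_id") %in% names(df))) {
    stop("GTF lacks type/transcript_id/gene_id attributes: ", path)
  }
  # to 0-based half-open
  df$start0 <- df$start - 1
  df$end0 <- df$end
  ex <- df[df$type == "exon", ]
  cds <- df[df$type %in% c("CDS", "stop_codon"), ]
  records <- list()
  n_noncoding <- 0L
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx, ]
    cc <- cds[cds$transcript_id == tx, ]
    if (nrow(cc) == 0L) {
      n_noncoding <- n_noncoding + 1L
      next
    }
    records[[length(records) + 1L]] <- list(
      gene_id = e$gene_id[1], transcript_id = tx, chrom = as.character(e$seqnames[1]),
      strand = as.character(e$strand[1]),
      exons = cbind(e$start0, e$end0), cds = c(min(cc$start0), max(cc$end0)))
  }
  list(records = records, n_noncoding = n_noncoding)
}

#' Choose one exemplar transcript per gene
#'
#' The exemplar is the transcript with the longest annotated 3'UTR for each
#' gene; ties are broken by the lexicographically smallest transcript id so
#' selection is deterministic.
#'
#' @param ann a [genome_annotation].
#' @return The annotation with `exemplar_of` filled
#'   (named `gene_id -> transcript_id`).
#' @export
select_exemplars <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  tt <- ann$tx_table
  ord <- order(tt$gene_id, -tt$utr3_length, tt$transcript_id)
  tt <- tt[ord, ]
  first <- !duplicated(tt$gene_id)
  ann$exemplar_of <- stats::setNames(tt$transcript_id[first], tt$gene_id[first])
  ann
}

#' Exemplar transcripts as a data frame
#'
#' @param ann a [genome_annotation] with exemplars selected.
#' @return `tx_table` rows for the exemplar transcripts only.
#' @export
exemplar_table <- function(ann) {
  if (length(ann$exemplar_of) == 0L) stop("exemplars not selected yet")
  tt <- ann$tx_table[match(ann$exemplar_of, ann$tx_table$transcript_id), ]
  rownames(tt) <- NULL
  tt
}

# transcript coordinate of genomic position g: number of exonic bases
# 5' of g along the mature transcript
.tcoord <- function(t, g) {
  ex <- t$exons
  if (t$strand == "+") {
    sum(pmax(0, pmin(ex[, 2], g) - ex[, 1]))
  } else {
    sum(pmax(0, ex[, 2] - pmax(ex[, 1], g + 1)))
  }
}

.is_exonic <- function(t, g) any(t$exons[, 1] <= g & g < t$exons[, 2])

#' Termination-codon-relative position of a genomic coordinate
#'
#' Offset 0 is the first base 3' of the stop codon; positive offsets run
#' downstream into the 3'UTR in transcript orientation, negative offsets
#' upstream into the CDS. `"spliced"` measures along the mature transcript
#' (the coordinate must be exonic), `"genomic"` along the chromosome.
#'
#' @param t a [transcript_model].
#' @param g genomic coordinate (0-based) within the transcript span.
#' @param mode `"spliced"` (default) or `"genomic"`.
#' @return Integer offset in nucleotides.
#' @export
tc_relative_position <- function(t, g, mode = c("spliced", "genomic")) {
  mode <- match.arg(mode)
  span <- c(t$exons[1, 1], t$exons[nrow(t$exons), 2])
  if (g < span[1] || g >= span[2]) {
    stop(sprintf("position %d outside transcript span [%d, %d)",
                 as.integer(g), as.integer(span[1]), as.integer(span[2])))
  }
  if (mode == "genomic") {
    return(if (t$strand == "+") g - (t$cds_end_genomic + 1)
           else (t$cds_end_genomic - 1) - g)
  }
  if (!.is_exonic(t, g)) {
    stop(sprintf("position %d is intronic in transcript %s (spliced mode)",
                 as.integer(g), t$transcript_id))
  }
  .tcoord(t, g) - (.tcoord(t, t$cds_end_genomic) + 1)
}

#' Extract the spliced 3'UTR sequence
#'
#' Returns the 3'UTR of a transcript in transcript orientation
#' (reverse-complemented for minus-strand transcripts), uppercased, with
#' RNA `U` normalized to `T`. The source may be a genome FASTA (named by
#' chromosome) or a transcript/3'UTR FASTA (named by transcript id): a
#' sequence named by the transcript id is taken as the spliced transcript
#' (its last `utr3_length` bases are used) or, when its length equals
#' `utr3_length`, as the 3'UTR itself.
#'
#' @param t a [transcript_model].
#' @param source a `Biostrings::DNAStringSet`, a named character vector, or
#'   a FASTA file path.
#' @return Character string of length `utr3_length`.
#' @export
utr3_sequence <- function(t, source) {
  seqs <- .as_seq_set(source)
  if (t$transcript_id %in% names(seqs)) {
    s <- .norm_seq(as.character(seqs[[t$transcript_id]]))
    if (nchar(s) < t$utr3_length) {
      stop(sprintf("sequence for %s shorter than annotated 3'UTR",
                   t$transcript_id))
    }
    return(substr(s, nchar(s) - t$utr3_length + 1L, nchar(s)))
  }
  if (!t$chrom %in% names(seqs)) {
    stop(sprintf("no sequence for %s or %s in source", t$transcript_id, t$chrom))
  }
  chromseq <- seqs[[t$chrom]]
  if (nrow(t$utr3_intervals) == 0L) return("")
  if (max(t$utr3_intervals[, 2]) > length(chromseq)) {
    stop(sprintf("chromosome %s shorter than annotation for %s",
                 t$chrom, t$transcript_id))
  }
  pieces <- apply(t$utr3_intervals, 1, function(iv) {
    as.character(Biostrings::subseq(chromseq, start = iv[1] + 1L, end = iv[2]))
  })
  s <- paste(pieces, collapse = "")
  if (t$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  .norm_seq(s)
}

.as_seq_set <- function(source) {
  if (inherits(source, "DNAStringSet")) return(source)
  if (is.character(source) && length(source) == 1L && file.exists(source)) {
    return(Biostrings::readDNAStringSet(source))
  }
  if (is.character(source) && !is.null(names(source))) {
    return(Biostrings::DNAStringSet(chartr("Uu", "Tt", source)))
  }
  stop("sequence source must be a DNAStringSet, named character vector, or FASTA path")
}

.norm_seq <- function(s) chartr("U", "T", toupper(s))

#' Spliced 3'UTR sequences for all exemplar transcripts
#'
#' @param ann a [genome_annotation] with exemplars selected.
#' @param source sequence source as in [utr3_sequence()].
#' @return Named character vector keyed by transcript id.
#' @export
utr3_sequences <- function(ann, source) {
  seqs <- .as_seq_set(source)
  txs <- ann$transcripts[ann$exemplar_of]
  out <- vapply(txs, utr3_sequence, character(1), source = seqs)
  stats::setNames(out, vapply(txs, `[[`, character(1), "transcript_id"))
}

#' Write the exemplar table as TSV
#'
#' Columns: gene_id, transcript_id, utr3_length.
#'
#' @param ann a [genome_annotation] with exemplars selected.
#' @param path output file.
#' @export
write_exemplar_table <- function(ann, path) {
  tt <- exemplar_table(ann)
  utils::write.table(tt[, c("gene_id", "transcript_id", "utr3_length")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
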