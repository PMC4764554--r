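#' @title Synthetic datasets with planted ground truth
#' @description Generates complete, internally consistent datasets —
#'   annotation, 3'UTR sequences, knockdown count matrices, CLIP peaks and
#'   decay time courses — with known truth labels, so every pipeline stage
#'   can be tested without external downloads. Counts follow a
#'   negative-binomial model (the standard RNA-seq noise family); CLIP
#'   peak centers on protected genes follow a truncated normal anchored
#'   just downstream of the termination codon. Identical config + seed
#'   reproduce byte-identical outputs; each generator draws from its own
#'   seed stream derived from `seed` so the components may be regenerated
#'   independently.
#' @name synthetic
NULL

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' four knockdown conditions with three replicates, 2-fold protection
#' effects with full rescue in the double knockdown, 2-fold
#' NMD-target response to siUPF1, negative-binomial dispersion 0.05,
#' log-normal 3'UTR lengths (median ~1.2 kb) with protected genes drawn
#' from a right-shifted distribution, protective hexamers planted within
#' 50 nt of the TC, decoy hexamers (uncoupled to protection) planted at
#' 50-100 nt on a fraction of unprotected genes, CLIP peak centers at
#' TC+100 +/- 40 nt on protected genes, and reporter half-lives of 120 and
#' 400 minutes sampled at 30/150/270/390 min after transcription shutoff.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes (one exemplar transcript each).
#' @param frac_protected fraction of genes protected by PTBP1.
#' @param frac_nmd_targets fraction of genes that are UPF1-responsive NMD
#'   targets.
#' @param effect_ptb fold decrease of protected genes upon PTBP1 knockdown.
#' @param effect_rescue fold increase in the double knockdown relative to
#'   siPTBP1 alone; `NULL` (default) means full rescue back to baseline.
#' @param effect_upf1 fold increase of NMD targets upon UPF1 knockdown.
#' @param effect_sd_log2 per-gene SD of the protection effect on the log2
#'   scale (0 = every protected gene exactly `effect_ptb`-fold).
#' @param nb_dispersion negative-binomial dispersion (0 = Poisson).
#' @param replicates replicates per condition.
#' @param utr3_meanlog,utr3_sdlog log-normal parameters of 3'UTR lengths
#'   (nt).
#' @param protected_utr3_shift multiplicative median shift of protected
#'   genes' 3'UTR lengths.
#' @param hexamer_offsets TC-relative offsets at which hexamers are
#'   planted on protected genes.
#' @param decoy_offsets offsets of uncoupled decoy hexamers.
#' @param decoy_frac fraction of unprotected genes receiving decoys.
#' @param peak_center_mean,peak_center_sd normal parameters (nt) of
#'   planted CLIP peak centers relative to the TC.
#' @param background_peak_rate expected background peaks per gene.
#' @param peak_width_range uniform range of peak widths (nt).
#' @param decay_half_lives true reporter half-lives (minutes).
#' @param decay_times sampling times (minutes after shutoff).
#' @param decay_replicates independent decay experiments per construct.
#' @param noise_sigma_log SD of log-normal measurement noise on decay
#'   abundances.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of
#'   baseline expression means.
#' @param intron_frac fraction of genes with one CDS intron.
#' @param intron_length intron length (nt).
#' @param utr5_length 5'UTR length (nt).
#' @param cds_length_range uniform range of CDS lengths (nt).
#' @param genes_per_chrom,gene_gap chromosome layout parameters.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 42L,
                              n_genes = 5000L,
                              frac_protected = 0.04,
                              frac_nmd_targets = 0.20,
                              effect_ptb = 2,
                              effect_rescue = NULL,
                              effect_upf1 = 2,
                              effect_sd_log2 = 0,
                              nb_dispersion = 0.05,
                              replicates = 3L,
                              utr3_meanlog = log(1200),
                              utr3_sdlog = 0.8,
                              protected_utr3_shift = 1.4,
                              hexamer_offsets = c(8L, 30L),
                              decoy_offsets = c(60L, 82L),
                              decoy_frac = 0.10,
                              peak_center_mean = 100,
                              peak_center_sd = 40,
                              background_peak_rate = 0.3,
                              peak_width_range = c(30L, 120L),
                              decay_half_lives = c(120, 400),
                              decay_times = c(30, 150, 270, 390),
                              decay_replicates = 3L,
                              noise_sigma_log = 0.1,
                              baseline_meanlog = log(200),
                              baseline_sdlog = 1,
                              intron_frac = 0.2,
                              intron_length = 800L,
                              utr5_length = 200L,
                              cds_length_range = c(600L, 3000L),
                              genes_per_chrom = 250L,
                              gene_gap = 2000L) {
  cfg <- as.list(environment())
  fr <- c(cfg$frac_protected, cfg$frac_nmd_targets, cfg$decoy_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$frac_protected + cfg$frac_nmd_targets > 1) {
    stop("protected and NMD-target fractions must sum to <= 1")
  }
  pos <- c(cfg$effect_ptb, cfg$effect_upf1, cfg$utr3_sdlog,
           cfg$protected_utr3_shift, cfg$peak_center_sd,
           cfg$decay_half_lives, cfg$baseline_sdlog)
  if (any(pos <= 0)) stop("scale parameters must be positive")
  if (cfg$nb_dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$replicates < 1L) stop("need >= 1 replicate")
  structure(cfg, class = "simulation_config")
}

.rand_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# sequence of length L with no hexamer occurrence, by rejection sampling
.hexamer_free_seq <- function(L, hexamers, max_try = 200L) {
  for (i in seq_len(max_try)) {
    s <- .rand_seq(L)
    if (nrow(scan_hexamers(s, hexamers)) == 0L) return(s)
  }
  stop("rejection sampling failed; lower the pyrimidine content of the ",
       "background composition or shorten the constrained region")
}

.plant_motifs <- function(s, offsets, hexamers) {
  for (o in offsets) {
    m <- sample(hexamers, 1L)
    substr(s, o + 1L, o + 6L) <- m
  }
  s
}

#' Simulate annotation, 3'UTR sequences and truth labels
#'
#' Creates one exemplar transcript per gene on a tandem chromosome layout
#' (a fraction carry one CDS intron; 3'UTRs are contiguous in genomic
#' coordinates). Protected genes draw 3'UTR lengths from a right-shifted
#' distribution and carry planted hexamers at the configured TC-proximal
#' offsets; decoy genes carry uncoupled hexamers at 50-100 nt; all other
#' 3'UTRs are rejection-sampled to contain no set hexamer within the first
#' 400 nt.
#'
#' @param cfg a [simulation_config].
#' @param sequences generate 3'UTR sequences (set `FALSE` to skip the
#'   sequence stage when only geometry is needed).
#' @return List with `annotation` (a [genome_annotation] with exemplars
#'   selected), `utr3_seq` (named character vector keyed by transcript
#'   id, or `NULL`), and `labels` (data frame: `gene_id`,
#'   `transcript_id`, `label` in protected/nmd_target/background, `decoy`,
#'   `utr3_length`).
#' @export
simulate_annotation_and_sequences <- function(cfg, sequences = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  tx_id <- sprintf("T%05d", seq_len(n))

  n_prot <- round(cfg$frac_protected * n)
  n_nmd <- round(cfg$frac_nmd_targets * n)
  lab <- rep("background", n)
  pick <- sample.int(n, n_prot + n_nmd)
  lab[pick[seq_len(n_prot)]] <- "protected"
  if (n_nmd > 0) lab[pick[n_prot + seq_len(n_nmd)]] <- "nmd_target"
  decoy <- rep(FALSE, n)
  unprot <- which(lab != "protected")
  decoy[sample(unprot, round(cfg$decoy_frac * length(unprot)))] <- TRUE

  min_len <- max(c(cfg$hexamer_offsets, cfg$decoy_offsets)) + 30L
  utr3_len <- round(stats::rlnorm(n, cfg$utr3_meanlog, cfg$utr3_sdlog))
  shift <- lab == "protected"
  utr3_len[shift] <- round(stats::rlnorm(sum(shift),
                                         cfg$utr3_meanlog +
                                           log(cfg$protected_utr3_shift),
                                         cfg$utr3_sdlog))
  utr3_len <- pmax(utr3_len, min_len)

  cds_len <- sample(cfg$cds_length_range[1]:cfg$cds_length_range[2], n,
                    replace = TRUE)
  has_intron <- stats::runif(n) < cfg$intron_frac
  strand <- sample(c("+", "-"), n, replace = TRUE)

  transcripts <- vector("list", n)
  cursor <- 0
  chrom_idx <- 0L
  for (i in seq_len(n)) {
    if ((i - 1L) %% cfg$genes_per_chrom == 0L) {
      chrom_idx <- chrom_idx + 1L
      cursor <- 0
    }
    ilen <- if (has_intron[i]) cfg$intron_length else 0L
    u5 <- cfg$utr5_length
    cds <- cds_len[i]
    L <- utr3_len[i]
    s <- cursor
    span <- u5 + cds + ilen + L
    if (strand[i] == "+") {
      cds_lo <- s + u5
      cds_hi <- s + u5 + cds + ilen
      exons <- if (ilen > 0) {
        brk <- s + u5 + floor(cds / 2)
        rbind(c(s, brk), c(brk + ilen, s + span))
      } else rbind(c(s, s + span))
    } else {
      cds_lo <- s + L
      cds_hi <- s + L + cds + ilen
      exons <- if (ilen > 0) {
        brk <- s + L + floor(cds / 2)
        rbind(c(s, brk), c(brk + ilen, s + span))
      } else rbind(c(s, s + span))
    }
    transcripts[[i]] <- transcript_model(
      tx_id[i], gene_id[i], sprintf("chr%d", chrom_idx), strand[i],
      exons, c(cds_lo, cds_hi))
    cursor <- s + span + cfg$gene_gap
  }
  ann <- select_exemplars(genome_annotation(transcripts))

  utr3_seq <- NULL
  if (sequences) {
    hex <- ptbp1_hexamers()
    utr3_seq <- character(n)
    for (i in seq_len(n)) {
      L <- utr3_len[i]
      R <- min(L, 400L)
      region <- .hexamer_free_seq(R, hex)
      if (lab[i] == "protected") {
        region <- .plant_motifs(region, cfg$hexamer_offsets, hex)
      } else if (decoy[i]) {
        region <- .plant_motifs(region, cfg$decoy_offsets, hex)
      }
      tail_seq <- if (L > R) .rand_seq(L - R) else ""
      utr3_seq[i] <- paste0(region, tail_seq)
    }
    names(utr3_seq) <- tx_id
  }

  labels <- data.frame(gene_id = gene_id, transcript_id = tx_id,
                       label = lab, decoy = decoy, utr3_length = utr3_len,
                       stringsAsFactors = FALSE)
  list(annotation = ann, utr3_seq = utr3_seq, labels = labels)
}

#' Simulate the 3'UTR count matrix
#'
#' Baseline gene means are log-normal; condition multipliers plant the
#' effects (protected: 1/`effect_ptb` in siPTBP1, rescued toward baseline
#' in the double knockdown; NMD targets: `effect_upf1`-fold up in siUPF1
#' and in the double knockdown); counts are negative-binomially dispersed
#' (Poisson when dispersion is 0). Deterministic given the config seed.
#'
#' @param cfg a [simulation_config].
#' @param labels truth-label data frame from
#'   [simulate_annotation_and_sequences()].
#' @return A [count_table].
#' @export
simulate_counts <- function(cfg, labels) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(labels)
  base <- stats::rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
  prot <- labels$label == "protected"
  nmd <- labels$label == "nmd_target"

  e_log2 <- rep(0, n)
  e_log2[prot] <- if (cfg$effect_sd_log2 > 0) {
    pmax(0.3, stats::rnorm(sum(prot), log2(cfg$effect_ptb), cfg$effect_sd_log2))
  } else log2(cfg$effect_ptb)
  rescue_fold <- if (is.null(cfg$effect_rescue)) 2^e_log2 else
    rep(cfg$effect_rescue, n)

  mult <- cbind(
    siNT = rep(1, n),
    siUPF1 = ifelse(nmd, cfg$effect_upf1, 1),
    siPTBP1 = ifelse(prot, 2^-e_log2, 1),
    siPTBP1_siUPF1 = ifelse(prot, 2^-e_log2 * rescue_fold,
                            ifelse(nmd, cfg$effect_upf1, 1))
  )
  conds <- colnames(mult)
  samples <- as.vector(t(outer(conds, seq_len(cfg$replicates), paste, sep = "_")))
  counts <- matrix(0L, n, length(samples),
                   dimnames = list(labels$gene_id, samples))
  for (s in samples) {
    cond <- sub("_[0-9]+$", "", s)
    mu <- base * mult[, cond]
    counts[, s] <- if (cfg$nb_dispersion > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
    } else {
      stats::rpois(n, mu)
    }
  }
  design <- data.frame(
    sample = samples,
    condition = sub("_[0-9]+$", "", samples),
    replicate = as.integer(sub("^.*_", "", samples)),
    stringsAsFactors = FALSE)
  count_table(counts, design)
}

#' Simulate CLIP peaks
#'
#' Every protected gene receives one peak whose TC-relative center is
#' drawn from Normal(`peak_center_mean`, `peak_center_sd`) truncated to
#' the 3'UTR; background peaks land uniformly over transcript spans at
#' rate `background_peak_rate` per gene. Widths are uniform over
#' `peak_width_range` (all below the 500-nt filter).
#'
#' @param cfg a [simulation_config].
#' @param labels truth labels.
#' @param ann the matching [genome_annotation].
#' @return List with `peaks` (a `clip_peaks` data frame) and `truth`
#'   (data frame of planted `gene_id`, `center_offset`).
#' @export
simulate_clip_peaks <- function(cfg, labels, ann) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 2L)
  tt <- ann$tx_table
  tt <- tt[match(labels$transcript_id, tt$transcript_id), ]

  draw_trunc <- function(m, sd, hi) {
    repeat {
      x <- stats::rnorm(1, m, sd)
      if (x >= 0 && x <= hi) return(x)
    }
  }
  rows <- list()
  truth <- list()
  prot_ix <- which(labels$label == "protected")
  for (i in prot_ix) {
    t <- ann$transcripts[[labels$transcript_id[i]]]
    off <- round(draw_trunc(cfg$peak_center_mean, cfg$peak_center_sd,
                            t$utr3_length - 1))
    center <- if (t$strand == "+") t$cds_end_genomic + 1 + off else
      t$cds_end_genomic - 1 - off
    w <- sample(cfg$peak_width_range[1]:cfg$peak_width_range[2], 1L)
    start <- max(0, center - floor(w / 2))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = t$chrom, start = start, end = start + w, strand = t$strand,
      weight = sample(5:50, 1L), stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = labels$gene_id[i], center_offset = off,
      stringsAsFactors = FALSE)
  }
  n_bg <- round(cfg$background_peak_rate * nrow(labels))
  if (n_bg > 0) {
    gi <- sample.int(nrow(labels), n_bg, replace = TRUE)
    for (i in gi) {
      t <- ann$transcripts[[labels$transcript_id[i]]]
      span <- c(t$exons[1, 1], t$exons[nrow(t$exons), 2])
      center <- sample(span[1]:(span[2] - 1L), 1L)
      w <- sample(cfg$peak_width_range[1]:cfg$peak_width_range[2], 1L)
      start <- max(0, center - floor(w / 2))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = t$chrom, start = start, end = start + w, strand = t$strand,
        weight = sample(5:50, 1L), stringsAsFactors = FALSE)
    }
  }
  pk <- do.call(rbind, rows)
  peaks <- clip_peaks(pk$chrom, pk$start, pk$end, pk$strand, pk$weight)
  list(peaks = peaks,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(gene_id = character(0), center_offset = numeric(0)))
}

#' Simulate reporter decay time courses
#'
#' `abundance(t) = exp(-ln2 t / t_half) * exp(noise)`, noise ~
#' Normal(0, `noise_sigma_log`), sampled at the configured times for each
#' construct and replicate.
#'
#' @param cfg a [simulation_config].
#' @return List with `timecourses` (data frame: `construct`, `replicate`,
#'   `time`, `abundance`) and `truth` (construct, true `t_half`).
#' @export
simulate_decay <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 3L)
  grid <- expand.grid(time = cfg$decay_times,
                      replicate = seq_len(cfg$decay_replicates),
                      t_half = cfg$decay_half_lives)
  grid$construct <- sprintf("thalf_%g", grid$t_half)
  noise <- stats::rnorm(nrow(grid), 0, cfg$noise_sigma_log)
  grid$abundance <- exp(-log(2) * grid$time / grid$t_half) * exp(noise)
  list(
    timecourses = data.frame(construct = grid$construct,
                             replicate = grid$replicate,
                             time = grid$time, abundance = grid$abundance,
                             stringsAsFactors = FALSE),
    truth = data.frame(construct = sprintf("thalf_%g", cfg$decay_half_lives),
                       t_half = cfg$decay_half_lives,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a complete dataset
#'
#' @param cfg a [simulation_config].
#' @param sequences generate 3'UTR sequences.
#' @return List with `annotation`, `utr3_seq`, `labels`, `counts`,
#'   `peaks`, `peak_truth`, `decay`, `decay_truth`, and the `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config(), sequences = TRUE) {
  a <- simulate_annotation_and_sequences(cfg, sequences = sequences)
  counts <- simulate_counts(cfg, a$labels)
  pk <- simulate_clip_peaks(cfg, a$labels, a$annotation)
  dk <- simulate_decay(cfg)
  list(annotation = a$annotation, utr3_seq = a$utr3_seq, labels = a$labels,
       counts = counts, peaks = pk$peaks, peak_truth = pk$truth,
       decay = dk$timecourses, decay_truth = dk$truth, config = cfg)
}
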