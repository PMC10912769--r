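# Sequence synthesis helpers -------------------------------------------------

# iid nucleotide string with a given expected GC fraction
sample_seq <- function(n, gc) {
  if (n <= 0) return("")
  is_gc <- stats::runif(n) < gc
  b <- character(n)
  b[is_gc] <- sample(c("G", "C"), sum(is_gc), replace = TRUE)
  b[!is_gc] <- sample(c("A", "T"), sum(!is_gc), replace = TRUE)
  paste(b, collapse = "")
}

# CDS with an exact GC base count: ATG start, sampled stop codon, internal
# stops removed by within-codon base permutation (GC-preserving).
# pos_weights biases where GC lands across the three codon positions, so
# that per-position GC varies between genes beyond the total (as in real
# coding sequence, where wobble positions carry most of the GC variation).
synth_cds <- function(len, gc_target, gene_id, pos_weights = c(1, 1, 1)) {
  if (len %% 3 != 0) stop("CDS length must be a multiple of 3")
  if (len < 30)
    stop("CDS too short to synthesize for gene ", gene_id)
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
  gc_stop <- if (stop_codon == "TAA") 0L else 1L
  n_int <- len - 6L
  need <- round(gc_target * len) - 1L - gc_stop  # ATG carries one G
  if (need < 0 || need > n_int ||
      abs((need + 1L + gc_stop) / len - gc_target) > 0.02)
    stop("unreachable GC target ", signif(gc_target, 3), " for gene ", gene_id)
  base <- character(n_int)
  # internal sequence starts at codon 2, position 1
  cpos <- ((seq_len(n_int) - 1L) %% 3L) + 1L
  gc_idx <- if (need > 0)
    sample.int(n_int, need, prob = pos_weights[cpos]) else integer(0)
  is_gc <- rep(FALSE, n_int); is_gc[gc_idx] <- TRUE
  base[is_gc] <- sample(c("G", "C"), sum(is_gc), replace = TRUE)
  base[!is_gc] <- sample(c("A", "T"), sum(!is_gc), replace = TRUE)
  codons <- c("ATG",
              substring(paste(base, collapse = ""),
                        seq(1, n_int - 2, 3), seq(3, n_int, 3)),
              stop_codon)
  n_cod <- length(codons)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq(2, n_cod - 1)) {
    while (codons[i] %in% stops) {
      codons[i] <- paste(sample(strsplit(codons[i], "")[[1]]), collapse = "")
    }
  }
  paste(codons, collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Transcriptome generator -----------------------------------------------------

#' Simulate a toy transcriptome with planted GC-dependent regulation
#'
#' Generates `n_genes` single-transcript genes on one synthetic chromosome.
#' Every gene has a 5'UTR, a CDS (ATG start, terminal stop, length a multiple
#' of 3, realized GC within 0.02 of a target sampled from `gc_range`), a
#' 3'UTR, and with probability one half a single GT..AG intron inserted at a
#' codon boundary inside the CDS. Roughly 30% of genes are placed on the
#' minus strand. Alongside the annotation and sequences, a ground-truth table
#' is returned: each gene's regulation class (`TE_down` / `TE_up` /
#' `unchanging`), its realized coding-sequence GC, its planted per-timepoint
#' log2 fold changes for RNA-seq and Ribo-seq, and the sign of its 5'
#' coverage-shift under depletion (`+1` drift 3'-ward for degraded genes,
#' `-1` drift 5'-ward for stabilized genes, `0` otherwise).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_transcriptome`: list with elements
#'   `models` (named list of `transcript_model`), `genome`
#'   ([Biostrings::DNAStringSet], one chromosome `"chrsim"`), `transcripts`
#'   (mature sense sequences), and `truth` (class `sim_truth`; see Details).
#' @details `truth` is a list with `genes` (data frame: `gene_id`, `class`,
#'   `gc_cds`, `tx_len`, `effect_lfc`, `shift_sign`), `lfc_rna` and
#'   `lfc_ribo` (gene-by-timepoint matrices of planted log2 fold changes in
#'   depleted relative to control samples), `timepoints_h` and the `config`.
#'   The same configuration (including its seed) reproduces identical output.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("g%05d", seq_len(n))

  # regulation classes: exact planted fractions
  n_down <- round(n * config$frac_te_down)
  n_up <- round(n * config$frac_te_up)
  cls <- rep("unchanging", n)
  reg_idx <- sample.int(n, n_down + n_up)
  cls[reg_idx[seq_len(n_down)]] <- "TE_down"
  if (n_up > 0) cls[reg_idx[n_down + seq_len(n_up)]] <- "TE_up"

  gc_target <- stats::runif(n, config$gc_range[1], config$gc_range[2])
  L <- round(stats::runif(n, config$coverage_len_range[1],
                          config$coverage_len_range[2]))
  strand <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.7, 0.3))
  has_intron <- stats::runif(n) < 0.5

  models <- vector("list", n)
  tx_seqs <- character(n)
  chrom_parts <- character(n)
  gc_real <- numeric(n)
  reg_lens <- matrix(0L, n, 4, dimnames = list(NULL, c("utr5", "cds",
                                                       "utr3", "intron")))
  offset <- 0L  # 0-based start of next gene body on the chromosome

  for (i in seq_len(n)) {
    utr5_len <- max(40L, round(0.12 * L[i]))
    utr3_len <- max(60L, round(0.25 * L[i]))
    cds_len <- L[i] - utr5_len - utr3_len
    cds_len <- cds_len - cds_len %% 3L
    utr3_len <- L[i] - utr5_len - cds_len
    utr5 <- sample_seq(utr5_len, min(max(gc_target[i] +
                                           stats::rnorm(1, 0, 0.05), 0.1), 0.9))
    utr3 <- sample_seq(utr3_len, min(max(gc_target[i] +
                                           stats::rnorm(1, 0, 0.05), 0.1), 0.9))
    # per-gene codon-position GC bias, tilted toward the wobble position
    pw <- stats::rgamma(3, shape = c(2, 2, 5))
    cds <- synth_cds(cds_len, gc_target[i], ids[i], pos_weights = pw)
    gc_real[i] <- gc_content(cds)
    mature <- paste0(utr5, cds, utr3)

    # optional intron at a codon boundary strictly inside the CDS
    ilen <- 0L; ins <- NA_integer_; intron <- ""
    if (has_intron[i]) {
      ilen <- sample(80:400, 1)
      k <- sample(seq(5L, cds_len %/% 3L - 5L), 1)  # codon index
      ins <- utr5_len + 3L * k                       # tx coordinate, 0-based
      intron <- paste0("GT", sample_seq(ilen - 4L, 0.4), "AG")
    }
    pre_len <- L[i] + ilen
    pre <- if (ilen > 0)
      paste0(substr(mature, 1, ins), intron,
             substr(mature, ins + 1, L[i]))
    else mature

    # exons in pre-mRNA (sense) 0-based half-open coordinates
    exons_pre <- if (ilen > 0)
      rbind(c(0L, ins), c(ins + ilen, pre_len))
    else rbind(c(0L, pre_len))
    # CDS pieces in pre coordinates (tx [utr5_len, utr5_len + cds_len))
    cds_tx <- c(utr5_len, utr5_len + cds_len)
    to_pre <- function(p) p + ifelse(ilen > 0 & p > ins, ilen, 0L)
    cds_pre <- if (ilen > 0 && ins > cds_tx[1] && ins < cds_tx[2])
      rbind(c(cds_tx[1], ins), c(ins + ilen, to_pre(cds_tx[2])))
    else rbind(c(to_pre(cds_tx[1]), to_pre(cds_tx[2])))

    # place on the chromosome: spacer then body (reverse-complemented if -)
    spacer <- sample_seq(100L, 0.45)
    body <- if (strand[i] == "+") pre else revcomp_chr(pre)
    body_start <- offset + 100L  # 0-based genomic start of the body
    chrom_parts[i] <- paste0(spacer, body)
    offset <- offset + 100L + pre_len

    pre2gen <- function(m) {
      # pre [s,e) -> genomic 1-based closed (start, end)
      if (strand[i] == "+")
        cbind(body_start + m[, 1] + 1L, body_start + m[, 2])
      else
        cbind(body_start + (pre_len - m[, 2]) + 1L,
              body_start + (pre_len - m[, 1]))
    }
    ex_g <- pre2gen(exons_pre)
    cds_g <- pre2gen(cds_pre)
    models[[i]] <- make_transcript_model(
      gene_id = ids[i], transcript_id = sub("^g", "t", ids[i]),
      chrom = "chrsim", strand = strand[i],
      exon_starts = ex_g[, 1], exon_ends = ex_g[, 2],
      cds_starts = cds_g[, 1], cds_ends = cds_g[, 2])
    tx_seqs[i] <- mature
    reg_lens[i, ] <- c(utr5_len, cds_len, utr3_len, ilen)
  }
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")

  genome <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
  names(genome) <- "chrsim"
  transcripts <- Biostrings::DNAStringSet(tx_seqs)
  names(transcripts) <- ids

  # planted per-timepoint log2 fold changes (depleted vs control)
  prof <- trajectory_profiles(config$timepoints_h)
  w <- gc_effect_weight(gc_real, config)
  eff <- config$effect_size_lfc * w
  sgn <- ifelse(cls == "TE_down", -1, ifelse(cls == "TE_up", 1, 0))
  lfc_ribo <- outer(sgn * eff, prof$ribo)
  lfc_rna <- outer(-sgn * eff, prof$rna)  # anti-correlated with Ribo
  dimnames(lfc_ribo) <- dimnames(lfc_rna) <-
    list(ids, paste0("t", config$timepoints_h))

  truth <- structure(list(
    genes = data.frame(gene_id = ids, class = cls, gc_cds = gc_real,
                       tx_len = L,
                       effect_lfc = ifelse(cls == "unchanging", 0, eff),
                       shift_sign = ifelse(cls == "TE_up", 1L,
                                           ifelse(cls == "TE_down", -1L, 0L)),
                       stringsAsFactors = FALSE),
    lfc_rna = lfc_rna, lfc_ribo = lfc_ribo,
    timepoints_h = config$timepoints_h, config = config),
    class = "sim_truth")
  rl <- cbind(
    utr5 = reg_lens[, "utr5"], start_window = 25L, cds = reg_lens[, "cds"],
    stop_window = 25L, intron = reg_lens[, "intron"], utr3 = reg_lens[, "utr3"])
  rownames(rl) <- ids
  attr(truth, "region_lengths") <- rl

  structure(list(models = models, genome = genome, transcripts = transcripts,
                 truth = truth),
            class = "sim_transcriptome")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$genes), "genes;",
      sum(x$genes$class == "TE_down"), "TE_down,",
      sum(x$genes$class == "TE_up"), "TE_up\n")
  invisible(x)
}

#' @export
print.sim_transcriptome <- function(x, ...) {
  cat("sim_transcriptome:", length(x$models), "transcripts on",
      length(x$genome), "chromosome(s)\n")
  print(x$truth)
  invisible(x)
}

#' Write a simulated transcriptome to disk
#'
#' Emits `genome.fa`, `transcripts.fa`, `annotation.gtf` (1-based closed,
#' standard GTF; the CDS features include the stop codon) and `truth.tsv`
#' into `dir`. Byte-identical output for identical configurations.
#'
#' @param sim a `sim_transcriptome` from [simulate_transcriptome()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_transcriptome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(sim$transcripts, file.path(dir, "transcripts.fa"))
  rtracklayer::export(transcriptome_gtf(sim$models),
                      file.path(dir, "annotation.gtf"), format = "gtf")
  truth <- cbind(sim$truth$genes,
                 stats::setNames(as.data.frame(sim$truth$lfc_rna),
                                 paste0("lfc_rna_", colnames(sim$truth$lfc_rna))),
                 stats::setNames(as.data.frame(sim$truth$lfc_ribo),
                                 paste0("lfc_ribo_", colnames(sim$truth$lfc_ribo))))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# GRanges of gene/transcript/exon/CDS/UTR features for GTF export
transcriptome_gtf <- function(models) {
  rows <- lapply(models, function(m) {
    ex <- m$exons
    tx_rng <- range(c(IRanges::start(ex), IRanges::end(ex)))
    feats <- data.frame(
      start = c(tx_rng[1], tx_rng[1], IRanges::start(ex)),
      end = c(tx_rng[2], tx_rng[2], IRanges::end(ex)),
      type = c("gene", "transcript", rep("exon", length(ex))),
      phase = NA_integer_, stringsAsFactors = FALSE)
    if (length(m$cds_genomic)) {
      # GTF frame: bases to skip to reach the next codon start, per CDS piece
      w_cds <- IRanges::width(m$cds_genomic)
      tx_ord <- if (m$strand == "+") seq_along(w_cds) else rev(seq_along(w_cds))
      before <- cumsum(c(0L, w_cds[tx_ord]))[seq_along(w_cds)]
      phase <- integer(length(w_cds))
      phase[tx_ord] <- (3L - before %% 3L) %% 3L
      feats <- rbind(feats, data.frame(
        start = IRanges::start(m$cds_genomic),
        end = IRanges::end(m$cds_genomic),
        type = rep("CDS", length(m$cds_genomic)),
        phase = phase))
      # UTR features from exon minus CDS, labelled by transcript side
      utr <- IRanges::setdiff(ex, m$cds_genomic)
      if (length(utr)) {
        cds_lo <- min(IRanges::start(m$cds_genomic))
        left <- IRanges::end(utr) < cds_lo
        utr_type <- if (m$strand == "+")
          ifelse(left, "five_prime_utr", "three_prime_utr")
        else ifelse(left, "three_prime_utr", "five_prime_utr")
        feats <- rbind(feats, data.frame(
          start = IRanges::start(utr), end = IRanges::end(utr),
          type = utr_type, phase = NA_integer_))
      }
    }
    feats$gene_id <- m$gene_id
    feats$transcript_id <- m$transcript_id
    feats$strand <- m$strand
    feats$chrom <- m$chrom
    feats
  })
  df <- do.call(rbind, rows)
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    type = df$type, source = "gcstab", phase = df$phase,
    gene_id = df$gene_id, transcript_id = df$transcript_id)
}
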