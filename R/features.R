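#' Build the per-gene feature table
#'
#' Computes the feature ledger used by the regression/importance stage: one
#' row per gene (using one representative transcript per gene: longest CDS,
#' then longest transcript, then lexicographically smallest id), with
#'
#' * `log_tpm` — log2(TPM + 1) from control RNA-seq samples;
#' * `base_TE` — log2 ratio of normalized Ribo-seq to RNA-seq counts in
#'   control samples at the earliest timepoint;
#' * `base_maturity` — log2 length-normalized ratio of intronic to exonic
#'   RNA-seq reads (requires region counts);
#' * `GCcds` and `GCpct_<region>` — GC fractions of the CDS, 5'/3' UTRs,
#'   25-nt windows around the start and stop codons, introns and non-coding
#'   internal exons;
#' * `log_len_<region>` — log2 region lengths;
#' * `posdens_<region>_<assay>` — region read count divided by region
#'   length, per assay (requires region counts);
#' * `GCpos1`/`GCpos2`/`GCpos3` — GC content at each codon position;
#' * `codonfr_<codon>` — frequencies of the 61 sense codons;
#' * `codon_optimality` — joined from an external table when provided.
#'
#' Missing regions give explicit `NA` values, never silent zeros. Genes
#' flagged for a CDS length not divisible by 3 get `NA` codon-derived
#' features; genes absent from the count matrix are dropped with a message.
#'
#' @param models named list of `transcript_model` objects (one or more per
#'   gene; a representative is chosen per gene).
#' @param genome [Biostrings::DNAStringSet] with the chromosome sequences.
#' @param cm a [count_matrix()] providing baseline control samples for both
#'   assays.
#' @param region_counts optional list with genes x regions matrices `rna`
#'   and `ribo` plus `region_lengths` (as produced by [simulate_counts()]);
#'   enables the density and maturity features.
#' @param optimality optional data frame with columns `gene_id` and `score`
#'   (an external codon-optimality measure), joined by gene id.
#' @return data frame of class `feature_table`, rownames = gene ids.
#' @export
build_feature_table <- function(models, genome, cm, region_counts = NULL,
                                optimality = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  models <- representative_transcripts(models)
  gene_ids <- vapply(models, `[[`, character(1), "gene_id")
  names(models) <- gene_ids

  present <- gene_ids %in% rownames(cm$counts)
  if (!all(present)) {
    message(sum(!present), " gene(s) absent from the count matrix; dropped")
    models <- models[present]
    gene_ids <- gene_ids[present]
  }
  n <- length(models)

  # baseline expression: control samples, earliest timepoint
  sf <- size_factors(cm$counts)
  t0 <- min(cm$samples$timepoint_h)
  base_sel <- function(a) cm$samples$condition == "ctrl" &
    cm$samples$timepoint_h == t0 & cm$samples$assay == a
  norm_mean <- function(a) {
    sel <- base_sel(a)
    rowMeans(sweep(cm$counts[gene_ids, sel, drop = FALSE], 2, sf[sel], `/`))
  }
  rna0 <- norm_mean("rna")
  ribo0 <- norm_mean("ribo")

  seqs <- lapply(models, transcript_seq, genome = genome)
  exonic_len <- vapply(models, `[[`, integer(1), "tx_len")
  rate <- rna0 / exonic_len
  tpm <- 1e6 * rate / sum(rate, na.rm = TRUE)

  regions <- c("utr5", "start_window", "cds", "stop_window", "utr3",
               "noncoding_internal_exons")
  reg_label <- c(utr5 = "utr5", start_window = "startwin", cds = "cds",
                 stop_window = "stopwin", utr3 = "utr3",
                 noncoding_internal_exons = "ncexon")

  ft <- data.frame(row.names = gene_ids)
  ft$log_tpm <- log2(tpm + 1)
  ft$base_TE <- ifelse(rna0 > 0 & ribo0 > 0, log2(ribo0 / rna0), NA_real_)

  for (r in regions) {
    gcs <- vapply(seq_len(n), function(i) {
      s <- region_seq(models[[i]], seqs[[i]], r)
      if (nchar(s)) gc_content(s) else NA_real_
    }, numeric(1))
    ft[[if (r == "cds") "GCcds" else paste0("GCpct_", reg_label[r])]] <- gcs
  }
  # intron GC from genomic sequence (sense strand)
  ft$GCpct_intron <- vapply(models, function(m) {
    if (!length(m$introns)) return(NA_real_)
    s <- paste(as.character(Biostrings::Views(genome[[m$chrom]], m$introns)),
               collapse = "")
    if (m$strand == "-") s <- revcomp_chr(s)
    gc_content(s)
  }, numeric(1))

  loglen <- function(len) ifelse(len > 0, log2(len), NA_real_)
  for (r in regions)
    ft[[paste0("log_len_", reg_label[r])]] <-
      loglen(vapply(models, region_len, integer(1), region = r))
  ft$log_len_intron <- loglen(vapply(models, function(m)
    sum(IRanges::width(m$introns)), numeric(1)))
  ft$log_len_tx <- loglen(exonic_len)

  if (!is.null(region_counts)) {
    lens <- region_counts$region_lengths[gene_ids, , drop = FALSE]
    for (a in c("rna", "ribo")) {
      rc <- region_counts[[a]][gene_ids, , drop = FALSE]
      for (r in colnames(rc)) {
        dens <- ifelse(lens[, r] > 0, rc[, r] / lens[, r], NA_real_)
        ft[[paste0("posdens_", reg_label[r] %||% r, "_", a)]] <- dens
      }
    }
    exn <- lens[, "utr5"] + lens[, "cds"] + lens[, "utr3"]
    mat <- ifelse(lens[, "intron"] > 0 & region_counts$rna[gene_ids, "cds"] +
                    region_counts$rna[gene_ids, "utr5"] +
                    region_counts$rna[gene_ids, "utr3"] > 0,
                  log2(((region_counts$rna[gene_ids, "intron"] + 0.5) /
                          lens[, "intron"]) /
                         ((region_counts$rna[gene_ids, "utr5"] +
                             region_counts$rna[gene_ids, "cds"] +
                             region_counts$rna[gene_ids, "utr3"] + 0.5) / exn)),
                  NA_real_)
    ft$base_maturity <- mat
  }

  gcpos <- t(vapply(seq_len(n), function(i) {
    m <- models[[i]]
    if (!m$cds_ok) return(c(NA_real_, NA_real_, NA_real_))
    gc_by_codon_position(region_seq(m, seqs[[i]], "cds"))
  }, numeric(3)))
  colnames(gcpos) <- c("GCpos1", "GCpos2", "GCpos3")
  ft <- cbind(ft, gcpos)

  cods <- t(vapply(seq_len(n), function(i) {
    m <- models[[i]]
    if (!m$cds_ok) return(rep(NA_real_, length(SENSE_CODONS)))
    codon_frequencies(region_seq(m, seqs[[i]], "cds"))
  }, numeric(length(SENSE_CODONS))))
  colnames(cods) <- paste0("codonfr_", SENSE_CODONS)
  ft <- cbind(ft, cods)

  if (!is.null(optimality)) {
    stopifnot(all(c("gene_id", "score") %in% names(optimality)))
    ft$codon_optimality <-
      optimality$score[match(gene_ids, optimality$gene_id)]
  }
  class(ft) <- c("feature_table", "data.frame")
  ft
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Write / read a feature table as TSV
#'
#' The TSV carries a header-metadata line (`# gcstab feature_table v1`)
#' naming the schema version, then a regular header and one row per gene.
#'
#' @param ft a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gcstab feature_table v1", con)
  utils::write.table(cbind(gene_id = rownames(ft), ft), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  rownames(ft) <- ft$gene_id
  ft$gene_id <- NULL
  for (j in seq_along(ft))  # all-NA columns read back as logical
    if (is.logical(ft[[j]])) ft[[j]] <- as.numeric(ft[[j]])
  class(ft) <- c("feature_table", "data.frame")
  ft
}
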