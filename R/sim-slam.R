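#' Simulate SLAM-seq conversion counts for a labeling/chase design
#'
#' Emulates a 4sU labeling experiment followed by a uridine chase under
#' control or depleted conditions. For a labeled sample at chase time `t`,
#' the fraction of molecules still carrying label is
#' `label_efficiency * exp(-k t)`, where the per-gene decay rate `k` is
#' `decay_rate_per_h`, multiplied by `stabilization_factor` for stabilized
#' (`TE_down`) genes and by `destabilization_factor` for degraded (`TE_up`)
#' genes in depleted samples. A still-labeled read is called converted with
#' probability `1 - (1 - conversion_prob)^ts_per_read` (at least one of its
#' reference T positions reads as C); every read additionally carries the
#' `background_conversion` chance of a spurious call. Unlabeled samples see
#' background conversion only. Total reads per gene and sample are negative
#' binomial around a log-normal baseline; converted-read counts are binomial
#' given the totals.
#'
#' @param truth a `sim_truth` object.
#' @param config the [sim_config()] used to build it.
#' @param chase_times_h chase durations to emit (hours).
#' @param n_replicates replicates per (labeling, condition, chase) cell;
#'   defaults to the configuration's replicate count.
#' @return an object of class `conversion_counts`: list with `total` and
#'   `tc` (genes x samples integer matrices, `0 <= tc <= total`) and
#'   `samples` (data frame: `sample_id`, `labeling` in `{"4sU","none"}`,
#'   `condition` in `{"ctrl","depleted"}`, `chase_time_h`, `replicate`).
#' @export
simulate_slam <- function(truth, config, chase_times_h = c(0, 8),
                          n_replicates = config$n_replicates) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(config$seed + 3L)
  genes <- truth$genes
  n <- nrow(genes)

  base <- 2^stats::rnorm(n, log2(config$reads_per_gene_slam), 0.6)
  k0 <- config$decay_rate_per_h
  k_mult <- function(condition) {
    if (condition == "ctrl") rep(1, n)
    else ifelse(genes$class == "TE_down", config$stabilization_factor,
                ifelse(genes$class == "TE_up",
                       config$destabilization_factor, 1))
  }
  q_read <- 1 - (1 - config$conversion_prob)^config$ts_per_read

  samples <- expand.grid(replicate = seq_len(n_replicates),
                         chase_time_h = chase_times_h,
                         condition = c("ctrl", "depleted"),
                         labeling = c("4sU", "none"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("labeling", "condition", "chase_time_h", "replicate")]
  samples$sample_id <- with(samples, paste(
    ifelse(labeling == "4sU", "lab", "unlab"), condition,
    paste0("t", chase_time_h), paste0("r", replicate), sep = "_"))

  total <- matrix(0L, n, nrow(samples),
                  dimnames = list(genes$gene_id, samples$sample_id))
  tc <- total
  size <- 1 / config$dispersion
  for (j in seq_len(nrow(samples))) {
    sj <- samples[j, ]
    tot <- stats::rnbinom(n, mu = base, size = size)
    p <- if (sj$labeling == "4sU") {
      labeled <- config$label_efficiency *
        exp(-k0 * k_mult(sj$condition) * sj$chase_time_h)
      labeled * q_read + (1 - labeled * q_read) * 0 +
        config$background_conversion
    } else rep(config$background_conversion, n)
    total[, j] <- tot
    tc[, j] <- stats::rbinom(n, tot, pmin(p, 1))
  }

  structure(list(total = total, tc = tc, samples = samples),
            class = "conversion_counts")
}

#' @export
print.conversion_counts <- function(x, ...) {
  cat("conversion_counts:", nrow(x$total), "genes x", ncol(x$total),
      "samples\n")
  print(table(labeling = x$samples$labeling, condition = x$samples$condition))
  invisible(x)
}

#' Write a synthetic SLAM-seq SAM file with planted T>C conversions
#'
#' Generates ungapped reads from the mature transcript sequences (each
#' transcript acts as its own reference "chromosome", sense strand), plants
#' T>C conversions with the given per-T probability, and writes a minimal
#' SAM file with QNAME/FLAG/RNAME/POS/MAPQ/CIGAR/SEQ fields and an MD tag.
#' This exists to exercise the read scanner ([scan_tc_reads()]); count
#' tables ([simulate_slam()]) are the primary SLAM output.
#'
#' @param transcripts [Biostrings::DNAStringSet] of reference transcript
#'   sequences.
#' @param sam_path output SAM path.
#' @param n_reads_per_tx reads per transcript.
#' @param read_len read length (nt).
#' @param conversion_prob per-T probability of a T>C conversion.
#' @param other_mismatch_prob per-base probability of a non-T>C sequencing
#'   mismatch (never T>C, never creating one).
#' @param seed integer seed.
#' @return invisibly, a data frame of per-read truth: `qname`, `rname`,
#'   `pos`, and `converted` (whether at least one T>C was planted).
#' @export
write_slam_sam <- function(transcripts, sam_path, n_reads_per_tx = 20,
                           read_len = 50, conversion_prob = 0.05,
                           other_mismatch_prob = 0.002, seed = 1L) {
  set.seed(seed)
  con <- file(sam_path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (tx in names(transcripts))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", tx, length(transcripts[[tx]])),
               con)
  truth <- list()
  r <- 0L
  for (tx in names(transcripts)) {
    ref <- as.character(transcripts[[tx]])
    L <- nchar(ref)
    if (L < read_len) next
    for (i in seq_len(n_reads_per_tx)) {
      r <- r + 1L
      pos <- sample.int(L - read_len + 1L, 1)
      refread <- substring(ref, pos, pos + read_len - 1L)
      bases <- strsplit(refread, "", fixed = TRUE)[[1]]
      is_t <- bases == "T"
      conv <- is_t & stats::runif(read_len) < conversion_prob
      bases[conv] <- "C"
      # benign mismatches on non-T positions (never A, C stays C etc.)
      other <- !is_t & stats::runif(read_len) < other_mismatch_prob
      for (k in which(other)) {
        alt <- setdiff(c("A", "G", "T"), bases[k])  # no new C from a T; no T>C
        bases[k] <- sample(alt, 1)
      }
      read <- paste(bases, collapse = "")
      md <- md_tag(refread, read)
      qname <- sprintf("read%06d", r)
      writeLines(paste(qname, 0L, tx, pos, 255L,
                       paste0(read_len, "M"), "*", 0L, 0L, read, "*",
                       paste0("MD:Z:", md), sep = "\t"), con)
      truth[[r]] <- data.frame(qname = qname, rname = tx, pos = pos,
                               converted = any(conv),
                               stringsAsFactors = FALSE)
    }
  }
  invisible(do.call(rbind, truth))
}

# MD tag for an ungapped alignment
md_tag <- function(ref, read) {
  rb <- strsplit(ref, "", fixed = TRUE)[[1]]
  qb <- strsplit(read, "", fixed = TRUE)[[1]]
  mm <- which(rb != qb)
  out <- character(0)
  prev <- 0L
  for (m in mm) {
    out <- c(out, as.character(m - prev - 1L), rb[m])
    prev <- m
  }
  out <- c(out, as.character(length(rb) - prev))
  paste(out, collapse = "")
}
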