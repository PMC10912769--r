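# SLAM-seq conversion analytics: a minimal SAM scanner that counts reads
# carrying sense-strand T>C mismatches against the reference, conversion
# fractions, the labeling x depletion NB-GLM stability test, and rank-sum
# comparisons of conversion fractions between regulation classes.

# parse a CIGAR string into (op, len) pairs
parse_cigar <- function(cigar) {
  if (cigar == "*") return(NULL)
  lens <- as.integer(strsplit(cigar, "[MIDNSHP=X]")[[1]])
  ops <- strsplit(gsub("[0-9]", "", cigar), "")[[1]]
  list(ops = ops, lens = lens)
}

# per-base (ref_pos, read_base) pairs of aligned positions; NULL if the
# CIGAR cannot be interpreted
aligned_pairs <- function(pos, cigar, seq) {
  cg <- parse_cigar(cigar)
  if (is.null(cg)) return(NULL)
  rp <- pos          # 1-based reference pointer
  qp <- 1L           # 1-based read pointer
  ref_pos <- integer(0)
  read_base <- character(0)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_along(cg$ops)) {
    op <- cg$ops[i]; len <- cg$lens[i]
    if (op %in% c("M", "=", "X")) {
      ref_pos <- c(ref_pos, seq.int(rp, length.out = len))
      read_base <- c(read_base, bases[seq.int(qp, length.out = len)])
      rp <- rp + len; qp <- qp + len
    } else if (op %in% c("I", "S")) {
      qp <- qp + len
    } else if (op %in% c("D", "N")) {
      rp <- rp + len
    } else if (op %in% c("H", "P")) {
      # consumes neither
    } else return(NULL)
  }
  list(ref_pos = ref_pos, read_base = read_base)
}

#' Scan a SAM file for T>C conversion reads
#'
#' Reads a minimal SAM file (QNAME/FLAG/RNAME/POS/CIGAR/SEQ columns; headers
#' ignored) and counts, per reference sequence, the total reads and the
#' reads carrying at least `min_conversions` sense-strand T>C mismatches
#' against the reference. Reference bases are taken from `reference`
#' directly (the MD tag, when present, is not required). For a gene on the
#' minus strand a sense T>C appears as A>G on the reference strand.
#'
#' @param sam_path path to a SAM file.
#' @param reference named [Biostrings::DNAStringSet] (names must match
#'   RNAME values).
#' @param gene_strand named character vector of gene strands (`"+"`/`"-"`);
#'   missing names default to `"+"` (the orientation of a 3'-end FWD
#'   protocol).
#' @param min_conversions minimum number of T>C mismatches for a read to
#'   count as converted (default 1).
#' @param min_baseq minimum base quality for a mismatch to count; `0`
#'   (default) disables quality filtering (QUAL column `*` is then allowed).
#' @return an object of class `conversion_counts` with one "sample": list
#'   with `total` and `tc` (one-column matrices per gene), `samples`, and a
#'   `qc` element counting unmapped/unparseable reads that were excluded.
#' @export
scan_tc_reads <- function(sam_path, reference, gene_strand = NULL,
                          min_conversions = 1L, min_baseq = 0L) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  genes <- names(reference)
  total <- stats::setNames(integer(length(genes)), genes)
  tc <- total
  skipped <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10) { skipped <- skipped + 1L; next }
    flag <- as.integer(f[2]); rname <- f[3]
    if (bitwAnd(flag, 4L) > 0 || rname == "*" || !rname %in% genes) {
      skipped <- skipped + 1L; next
    }
    ap <- aligned_pairs(as.integer(f[4]), f[6], f[10])
    if (is.null(ap) || !length(ap$ref_pos)) { skipped <- skipped + 1L; next }
    refseq <- reference[[rname]]
    if (max(ap$ref_pos) > length(refseq)) { skipped <- skipped + 1L; next }
    ref_base <- strsplit(as.character(refseq), "", fixed = TRUE)[[1]][ap$ref_pos]
    strand <- if (!is.null(gene_strand) && rname %in% names(gene_strand))
      gene_strand[[rname]] else "+"
    conv <- if (strand == "+") ref_base == "T" & ap$read_base == "C"
            else ref_base == "A" & ap$read_base == "G"
    if (min_baseq > 0 && f[11] != "*") {
      qual <- utf8ToInt(f[11]) - 33L
      # map aligned read bases back to their qualities
      cg <- parse_cigar(f[6])
      qp <- 1L; qidx <- integer(0)
      for (i in seq_along(cg$ops)) {
        op <- cg$ops[i]; len <- cg$lens[i]
        if (op %in% c("M", "=", "X")) {
          qidx <- c(qidx, seq.int(qp, length.out = len)); qp <- qp + len
        } else if (op %in% c("I", "S")) qp <- qp + len
      }
      conv <- conv & qual[qidx] >= min_baseq
    }
    total[rname] <- total[rname] + 1L
    if (sum(conv) >= min_conversions) tc[rname] <- tc[rname] + 1L
  }
  samples <- data.frame(sample_id = "sam", labeling = NA_character_,
                        condition = NA_character_, chase_time_h = NA_real_,
                        replicate = 1L, stringsAsFactors = FALSE)
  structure(list(total = matrix(total, ncol = 1,
                                dimnames = list(genes, "sam")),
                 tc = matrix(tc, ncol = 1, dimnames = list(genes, "sam")),
                 samples = samples, qc = c(excluded_reads = skipped)),
            class = "conversion_counts")
}

#' T>C conversion fractions
#'
#' @param cc a `conversion_counts` object.
#' @return genes x samples matrix of `tc / total`; `NA` where a gene has no
#'   reads in a sample.
#' @export
tc_fraction <- function(cc) {
  out <- cc$tc / cc$total
  out[cc$total == 0] <- NA_real_
  out
}

#' Differential mRNA stability test from SLAM-seq conversion counts
#'
#' Negative-binomial GLM on converted-read counts with labeling and
#' depletion status as covariates: full model
#' `~ labeling + condition`, reduced model `~ labeling` (assuming no
#' difference between control and depleted samples), likelihood-ratio test
#' of the depletion term. Size factors are computed from total (not
#' converted) read counts, so the depletion term measures conversion
#' enrichment rather than expression change. Genes are classed at
#' `p <= alpha` with direction given by the sign of the depletion
#' coefficient (positive = more label retained = stabilized).
#'
#' @param cc a `conversion_counts` object containing both labeling states
#'   and both conditions (typically the post-chase samples).
#' @param chase_time_h restrict to samples at this chase time (`NULL`: use
#'   all samples).
#' @param alpha significance cutoff on the unadjusted LRT p-value.
#' @param min_total_count genes with fewer summed converted reads are
#'   dropped.
#' @param min_genewise_df passed to [estimate_dispersions()].
#' @return data frame of class `stability_results`: `gene_id`, `base_mean`,
#'   `coef_depletion` (natural-log scale), `p`, `direction`
#'   (`stabilized`/`destabilized`), `stability_class`
#'   (`stabilized`/`destabilized`/`NS`).
#' @export
stability_test <- function(cc, chase_time_h = NULL, alpha = 0.05,
                           min_total_count = 10, min_genewise_df = 20) {
  samples <- cc$samples
  sel <- rep(TRUE, nrow(samples))
  if (!is.null(chase_time_h)) sel <- samples$chase_time_h == chase_time_h
  ss <- samples[sel, , drop = FALSE]
  if (length(unique(ss$labeling)) < 2 || length(unique(ss$condition)) < 2)
    stop("stability_test needs both labeling states and both conditions")
  ss$labeling <- factor(ss$labeling, levels = c("none", "4sU"))
  ss$condition <- factor(ss$condition, levels = c("ctrl", "depleted"))
  tc <- cc$tc[, sel, drop = FALSE]
  tot <- cc$total[, sel, drop = FALSE]
  keep <- rowSums(tc) >= min_total_count & rowSums(tot > 0) == ncol(tot)
  tc <- tc[keep, , drop = FALSE]
  sf <- size_factors(tot[keep, , drop = FALSE])

  lrt <- nb_lrt(tc, ss, ~ labeling + condition, ~ labeling, sf = sf,
                min_genewise_df = min_genewise_df)
  cf <- attr(lrt, "coefficients")[, "conditiondepleted"]
  direction <- ifelse(cf > 0, "stabilized", "destabilized")
  out <- data.frame(
    gene_id = lrt$gene_id, base_mean = lrt$base_mean,
    coef_depletion = cf, p = lrt$p_lrt, direction = direction,
    stability_class = ifelse(!is.na(lrt$p_lrt) & lrt$p_lrt <= alpha,
                             direction, "NS"),
    stringsAsFactors = FALSE)
  class(out) <- c("stability_results", "data.frame")
  out
}

#' Rank-sum comparison of conversion fractions between regulation classes
#'
#' One-sided Wilcoxon test of per-gene T>C conversion fractions between two
#' translation-regulation classes, restricted (per the intersection rule)
#' to genes significantly regulated in both translation and stability.
#'
#' @param fractions named numeric vector of per-gene conversion fractions
#'   (e.g. one column of [tc_fraction()]).
#' @param te_class named character vector of TE classes per gene.
#' @param stability_class optional named character vector of stability
#'   classes; when given, only genes with class != "NS" in both are used.
#' @param class_a,class_b the two TE classes to compare.
#' @param alternative one-sided alternative for `class_a` relative to
#'   `class_b`.
#' @return list with `p`, `n_a`, `n_b`; `p = NA` with a warning when a
#'   class is empty after intersection.
#' @export
group_fraction_test <- function(fractions, te_class, stability_class = NULL,
                                class_a = "TE_down", class_b = "NS",
                                alternative = "greater") {
  genes <- names(fractions)
  keep <- !is.na(fractions)
  if (!is.null(stability_class))
    keep <- keep & !is.na(stability_class[genes]) &
      stability_class[genes] != "NS"
  a <- fractions[keep & te_class[genes] == class_a]
  b <- fractions[keep & te_class[genes] == class_b]
  if (length(a) < 2 || length(b) < 2) {
    warning("empty (or singleton) class after intersection")
    return(list(p = NA_real_, n_a = length(a), n_b = length(b)))
  }
  list(p = stats::wilcox.test(a, b, alternative = alternative)$p.value,
       n_a = length(a), n_b = length(b))
}
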