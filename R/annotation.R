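#' Transcript model
#'
#' Internal constructor used both by [read_annotation()] and by the
#' transcriptome simulator. Genomic inputs follow the GTF convention
#' (1-based, closed intervals); all transcript-level coordinates held in the
#' model are 0-based, half-open. Conversion happens here, once, at the
#' boundary.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome (or synthetic contig) name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends genomic exon coordinates, 1-based closed.
#' @param cds_starts,cds_ends genomic CDS coordinates (the CDS is taken to
#'   include the stop codon); empty for non-coding transcripts.
#' @param window_nt width of the windows around the start and stop codons.
#' @param window_anchor `"center"` places the window symmetrically around the
#'   first base of the start (or stop) codon; `"downstream"` starts it there.
#'
#' @return an object of class `transcript_model`: a list with the genomic
#'   exon/CDS/intron structure, the mature transcript length, and a `regions`
#'   list of transcript-coordinate [IRanges::IRanges] for `utr5`,
#'   `start_window`, `cds`, `stop_window`, `utr3` and
#'   `noncoding_internal_exons`. `cds_ok` flags a CDS whose length is a
#'   positive multiple of 3.
#' @keywords internal
make_transcript_model <- function(gene_id, transcript_id, chrom, strand,
                                  exon_starts, exon_ends,
                                  cds_starts = integer(0),
                                  cds_ends = integer(0),
                                  window_nt = 25L,
                                  window_anchor = c("center", "downstream")) {
  window_anchor <- match.arg(window_anchor)
  stopifnot(strand %in% c("+", "-"), length(exon_starts) == length(exon_ends),
            all(exon_ends >= exon_starts))
  o <- order(exon_starts)
  exons <- IRanges::IRanges(start = exon_starts[o], end = exon_ends[o])
  if (length(exons) > 1 &&
      any(IRanges::start(exons)[-1] <= IRanges::end(exons)[-length(exons)]))
    stop("overlapping exons in transcript ", transcript_id)
  introns <- IRanges::gaps(exons)
  tx_len <- sum(IRanges::width(exons))

  # cumulative exon widths in transcript (5'->3') order
  w <- IRanges::width(exons)
  tx_order <- if (strand == "+") seq_along(w) else rev(seq_along(w))
  cum_before <- cumsum(c(0, w[tx_order]))[seq_along(w)]
  cum_before <- cum_before[order(tx_order)]   # indexed by genomic exon rank

  g2t <- function(gpos) {
    # genomic (1-based) -> transcript (0-based); NA off-exon
    vapply(gpos, function(g) {
      i <- which(g >= IRanges::start(exons) & g <= IRanges::end(exons))
      if (length(i) != 1) return(NA_integer_)
      off <- if (strand == "+") g - IRanges::start(exons)[i]
             else IRanges::end(exons)[i] - g
      as.integer(cum_before[i] + off)
    }, integer(1))
  }

  cds_span <- NULL
  cds_ok <- FALSE
  if (length(cds_starts)) {
    stopifnot(length(cds_starts) == length(cds_ends))
    tx_pos <- g2t(c(cds_starts, cds_ends))
    if (anyNA(tx_pos)) stop("CDS outside exons in transcript ", transcript_id)
    cds_span <- c(min(tx_pos), max(tx_pos) + 1L)  # 0-based half-open
    cds_len <- cds_span[2] - cds_span[1]
    expected <- sum(cds_ends - cds_starts + 1L)
    if (cds_len != expected)
      stop("CDS pieces are not contiguous in transcript coordinates for ",
           transcript_id)
    cds_ok <- cds_len > 0 && cds_len %% 3 == 0
    if (!cds_ok)
      warning("CDS length not a multiple of 3 for ", transcript_id,
              "; gene flagged and excluded from codon features")
  }

  # regions stored as 0-based half-open [start, end) integer matrices,
  # one row per piece; 0-row matrix = region absent
  empty_reg <- matrix(integer(0), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
  mk <- function(s, e) {
    s <- max(as.integer(s), 0L); e <- min(as.integer(e), tx_len)
    if (e <= s) empty_reg
    else matrix(c(s, e), 1, 2, dimnames = list(NULL, c("start", "end")))
  }

  regions <- list()
  if (!is.null(cds_span)) {
    s <- cds_span[1]; e <- cds_span[2]
    half <- window_nt %/% 2L
    stop_first <- e - 3L  # first base of stop codon
    regions$utr5 <- mk(0L, s)
    regions$cds <- mk(s, e)
    regions$utr3 <- mk(e, tx_len)
    if (window_anchor == "center") {
      regions$start_window <- mk(s - half, s - half + window_nt)
      regions$stop_window <- mk(stop_first - half, stop_first - half + window_nt)
    } else {
      regions$start_window <- mk(s, s + window_nt)
      regions$stop_window <- mk(stop_first, stop_first + window_nt)
    }
  } else {
    regions$utr5 <- empty_reg
    regions$cds <- empty_reg
    regions$utr3 <- empty_reg
    regions$start_window <- empty_reg
    regions$stop_window <- empty_reg
  }

  # internal exons whose transcript interval lies entirely outside the CDS
  nc <- empty_reg
  if (length(exons) > 2) {
    internal <- setdiff(seq_along(exons), c(1L, length(exons)))
    for (i in internal) {
      s0 <- cum_before[i]; e0 <- cum_before[i] + w[i]
      outside <- is.null(cds_span) || e0 <= cds_span[1] || s0 >= cds_span[2]
      if (outside) nc <- rbind(nc, c(s0, e0))
    }
  }
  regions$noncoding_internal_exons <- nc

  structure(list(
    gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
    strand = strand, exons = exons, introns = introns,
    cds_genomic = if (length(cds_starts))
      IRanges::IRanges(cds_starts, cds_ends) else IRanges::IRanges(),
    tx_len = as.integer(tx_len), cds_span = cds_span, cds_ok = cds_ok,
    regions = regions, cum_before = cum_before
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model", x$transcript_id, "(", x$gene_id, ") strand",
      x$strand, "\n  ", length(x$exons), "exon(s),", x$tx_len, "nt mature;",
      if (is.null(x$cds_span)) "no CDS"
      else paste0("CDS [", x$cds_span[1], ",", x$cds_span[2], ")"), "\n")
  invisible(x)
}

#' Convert between genomic and transcript coordinates
#'
#' `genomic_to_tx` maps genomic 1-based positions to 0-based transcript
#' positions (NA for intronic/intergenic positions); `tx_to_genomic` is its
#' inverse on `[0, tx_len)`.
#'
#' @param model a `transcript_model`.
#' @param pos positions to convert.
#' @return integer vector of converted positions.
#' @export
genomic_to_tx <- function(model, pos) {
  exons <- model$exons
  vapply(pos, function(g) {
    i <- which(g >= IRanges::start(exons) & g <= IRanges::end(exons))
    if (length(i) != 1) return(NA_integer_)
    off <- if (model$strand == "+") g - IRanges::start(exons)[i]
           else IRanges::end(exons)[i] - g
    as.integer(model$cum_before[i] + off)
  }, integer(1))
}

#' @rdname genomic_to_tx
#' @export
tx_to_genomic <- function(model, pos) {
  exons <- model$exons
  w <- IRanges::width(exons)
  vapply(pos, function(p) {
    if (is.na(p) || p < 0 || p >= model$tx_len) return(NA_integer_)
    i <- which(p >= model$cum_before & p < model$cum_before + w)
    off <- p - model$cum_before[i]
    as.integer(if (model$strand == "+") IRanges::start(exons)[i] + off
               else IRanges::end(exons)[i] - off)
  }, integer(1))
}

#' Read transcript models from a GTF file
#'
#' Parses a GTF annotation (via [rtracklayer::import()]) into a list of
#' `transcript_model` objects, one per transcript. Genomic 1-based closed
#' coordinates are converted to internal 0-based half-open transcript
#' coordinates; UTRs are always inferred from the exon-minus-CDS set
#' difference, so explicit UTR features are not required. The CDS is taken
#' to include the stop codon (transcripts whose CDS length is not a multiple
#' of 3 are flagged via `cds_ok = FALSE` and later excluded from codon
#' features).
#'
#' @param gtf_path path to a GTF file with `exon` (and usually `CDS`)
#'   features carrying `gene_id` and `transcript_id` attributes.
#' @param window_nt,window_anchor passed to the model constructor; see
#'   [make_transcript_model()].
#' @return named list of `transcript_model` objects (names are transcript
#'   ids); empty list for a GTF with no exon features.
#' @export
read_annotation <- function(gtf_path, window_nt = 25L,
                            window_anchor = c("center", "downstream")) {
  window_anchor <- match.arg(window_anchor)
  head_lines <- readLines(gtf_path, n = 100)
  if (!any(nzchar(head_lines) & !startsWith(head_lines, "#")))
    return(list())
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (!length(gr)) return(list())
  tx_ids <- unique(gr$transcript_id)
  models <- lapply(tx_ids, function(tid) {
    sub <- gr[gr$transcript_id == tid]
    ex <- sub[sub$type == "exon"]
    cds <- sub[sub$type == "CDS"]
    if (!length(ex)) return(NULL)
    make_transcript_model(
      gene_id = as.character(sub$gene_id[1]), transcript_id = tid,
      chrom = as.character(GenomicRanges::seqnames(sub))[1],
      strand = as.character(GenomicRanges::strand(ex))[1],
      exon_starts = GenomicRanges::start(ex), exon_ends = GenomicRanges::end(ex),
      cds_starts = GenomicRanges::start(cds), cds_ends = GenomicRanges::end(cds),
      window_nt = window_nt, window_anchor = window_anchor)
  })
  names(models) <- tx_ids
  models[!vapply(models, is.null, logical(1))]
}

#' Extract the mature (spliced, sense-strand) transcript sequence
#'
#' @param model a `transcript_model`.
#' @param genome a [Biostrings::DNAStringSet] holding the chromosome the
#'   model lives on.
#' @return a [Biostrings::DNAString] of length `tx_len`.
#' @export
transcript_seq <- function(model, genome) {
  chr <- genome[[model$chrom]]
  pieces <- as.character(Biostrings::Views(chr, model$exons))
  s <- Biostrings::DNAString(paste(pieces, collapse = ""))
  if (model$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Extract the sequence of a named transcript region
#'
#' @param model a `transcript_model`.
#' @param txseq the mature transcript sequence (from [transcript_seq()]).
#' @param region one of `"utr5"`, `"start_window"`, `"cds"`, `"stop_window"`,
#'   `"utr3"`, `"noncoding_internal_exons"`.
#' @return a character string (concatenated across region pieces); `""` if
#'   the region is absent.
#' @export
region_seq <- function(model, txseq, region) {
  reg <- model$regions[[region]]
  if (is.null(reg) || nrow(reg) == 0) return("")
  s <- as.character(txseq)
  paste(substring(s, reg[, 1] + 1L, reg[, 2]), collapse = "")
}

# total length of a region (sum over pieces), 0 if absent
region_len <- function(model, region) {
  reg <- model$regions[[region]]
  if (is.null(reg) || nrow(reg) == 0) return(0L)
  as.integer(sum(reg[, 2] - reg[, 1]))
}

#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T). `N` (and any other ambiguity code) is
#' excluded from the denominator. Empty or all-ambiguous sequences give `NA`.
#'
#' @param seq character vector of sequences (or objects coercible via
#'   `as.character`).
#' @return numeric vector of fractions in `[0, 1]`, or `NA`.
#' @export
#' @examples
#' gc_content(c("GCGC", "ATAT", "ATGCN"))
gc_content <- function(seq) {
  vapply(as.character(seq), function(s) {
    if (is.na(s) || !nchar(s)) return(NA_real_)
    b <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    acgt <- sum(b %in% c("A", "C", "G", "T"))
    if (acgt == 0) return(NA_real_)
    sum(b %in% c("G", "C")) / acgt
  }, numeric(1), USE.NAMES = FALSE)
}

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all64, c("TAA", "TAG", "TGA")))
}

#' Codon frequencies of a coding sequence
#'
#' Splits a frame-0 CDS into codons and returns the frequency of each of the
#' 61 sense codons among sense codons; stop codons (terminal or, with a
#' warning, internal) are excluded from both numerator and denominator. The
#' start codon is included in the tally.
#'
#' @param cds_sequence a CDS string whose length is a multiple of 3.
#' @return named numeric vector over the 61 sense codons, summing to 1 (or
#'   all `NA` when no sense codon is present).
#' @export
#' @examples
#' codon_frequencies("ATGAAATAA")[c("ATG", "AAA")]
codon_frequencies <- function(cds_sequence) {
  s <- toupper(as.character(cds_sequence))
  n <- nchar(s)
  if (n %% 3 != 0) stop("CDS length is not a multiple of 3")
  out <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  if (n == 0) return(out + NA_real_)
  codons <- substring(s, seq(1, n - 2, by = 3), seq(3, n, by = 3))
  stops <- codons %in% c("TAA", "TAG", "TGA")
  if (any(stops[-length(codons)]))
    warning("in-frame internal stop codon; excluded from the tally")
  sense <- codons[!stops & codons %in% SENSE_CODONS]
  if (!length(sense)) return(out + NA_real_)
  tab <- table(factor(sense, levels = SENSE_CODONS))
  out[] <- as.numeric(tab) / length(sense)
  out
}

#' GC content at each codon position
#'
#' @param cds_sequence a frame-0 CDS string (length a multiple of 3).
#' @return numeric vector `c(GCpos1, GCpos2, GCpos3)`: GC fraction over the
#'   bases at codon positions 1, 2 and 3, stop codons excluded.
#' @export
#' @examples
#' gc_by_codon_position("ATGGCA")
gc_by_codon_position <- function(cds_sequence) {
  s <- toupper(as.character(cds_sequence))
  n <- nchar(s)
  if (n %% 3 != 0) stop("CDS length is not a multiple of 3")
  if (n == 0) return(c(GCpos1 = NA_real_, GCpos2 = NA_real_, GCpos3 = NA_real_))
  codons <- substring(s, seq(1, n - 2, by = 3), seq(3, n, by = 3))
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  if (!length(codons))
    return(c(GCpos1 = NA_real_, GCpos2 = NA_real_, GCpos3 = NA_real_))
  out <- vapply(1:3, function(p)
    gc_content(paste(substring(codons, p, p), collapse = "")), numeric(1))
  names(out) <- c("GCpos1", "GCpos2", "GCpos3")
  out
}

# Representative transcript per gene: longest CDS, then longest transcript,
# then lexicographically smallest transcript id.
representative_transcripts <- function(models) {
  df <- data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    transcript_id = vapply(models, `[[`, character(1), "transcript_id"),
    cds_len = vapply(models, function(m)
      if (is.null(m$cds_span)) 0L else m$cds_span[2] - m$cds_span[1],
      integer(1)),
    tx_len = vapply(models, `[[`, integer(1), "tx_len"),
    stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, -df$cds_len, -df$tx_len, df$transcript_id), ]
  keep <- df$transcript_id[!duplicated(df$gene_id)]
  models[keep]
}
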