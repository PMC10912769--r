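# Binned summaries of the Ribo-seq/RNA-seq fold-change plane: per-cell
# means of a gene-level value, and per-cell mean displacement vectors
# between consecutive timepoints.

grid_edges <- function(lfc_rna, lfc_ribo, nbins, range = NULL) {
  if (is.null(range)) {
    m <- max(abs(c(lfc_rna, lfc_ribo)), na.rm = TRUE)
    m <- ceiling(m / 0.5) * 0.5  # symmetric, rounded up to 0.5
    range <- c(-m, m)
  }
  seq(range[1], range[2], length.out = nbins + 1)
}

# half-open [lo, hi) bin index; the last bin is closed on the right
bin_index <- function(x, edges) {
  n <- length(edges) - 1
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[x < edges[1] | x > edges[n + 1]] <- NA_integer_
  i
}

#' Bin gene-level values on the fold-change plane
#'
#' Divides the Ribo-seq/RNA-seq log2 fold-change coordinate system into
#' `nbins x nbins` half-open cells over a symmetric range and averages a
#' per-gene value within each occupied cell. Callers apply any significance
#' filter before binning (e.g. keeping only genes with significant TE
#' changes at the last timepoint).
#'
#' @param lfc_rna,lfc_ribo per-gene log2 fold changes (x and y coordinates).
#' @param value per-gene value to average (e.g. GCcds).
#' @param nbins bins per axis (70 by default).
#' @param range symmetric axis range `c(lo, hi)`; default
#'   `±max(|lfc|)` rounded up to the next 0.5.
#' @return an object of class `grid_summary`: data frame with `bin_i`
#'   (RNA axis), `bin_j` (Ribo axis), `n`, `mean_value`; attributes `edges`
#'   and `n_out_of_range`.
#' @export
bin_values <- function(lfc_rna, lfc_ribo, value, nbins = 70, range = NULL) {
  if (nbins < 2) stop("nbins must be at least 2")
  ok <- is.finite(lfc_rna) & is.finite(lfc_ribo)
  edges <- grid_edges(lfc_rna[ok], lfc_ribo[ok], nbins, range)
  i <- bin_index(lfc_rna, edges)
  j <- bin_index(lfc_ribo, edges)
  inr <- ok & !is.na(i) & !is.na(j)
  n_out <- sum(ok) - sum(inr)
  if (n_out > 0) message(n_out, " gene(s) outside the grid range")
  key <- paste(i[inr], j[inr])
  agg <- tapply(value[inr], key, mean)
  cnt <- tapply(value[inr], key, length)
  ij <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  out <- data.frame(bin_i = as.integer(ij[, 1]), bin_j = as.integer(ij[, 2]),
                    n = as.integer(cnt), mean_value = as.numeric(agg))
  out <- out[order(out$bin_i, out$bin_j), ]
  rownames(out) <- NULL
  attr(out, "edges") <- edges
  attr(out, "n_out_of_range") <- n_out
  class(out) <- c("grid_summary", "data.frame")
  out
}

#' Mean displacement vectors between consecutive timepoints
#'
#' Bins genes by their fold-change coordinates at the earlier timepoint and
#' computes, per occupied cell, the mean displacement vector to the later
#' timepoint (`d_rna`, `d_ribo`) and its Euclidean magnitude. Gene counts
#' per cell are retained for transparency scaling in vector plots.
#'
#' @param lfc_rna_prev,lfc_ribo_prev coordinates at the earlier timepoint.
#' @param lfc_rna_cur,lfc_ribo_cur coordinates (same genes) at the later
#'   timepoint.
#' @param nbins bins per axis.
#' @param range symmetric axis range; defaults as in [bin_values()].
#' @return a `grid_summary` data frame with `bin_i`, `bin_j`, `n`, `d_rna`,
#'   `d_ribo`, `magnitude`.
#' @export
vector_field <- function(lfc_rna_prev, lfc_ribo_prev,
                         lfc_rna_cur, lfc_ribo_cur,
                         nbins = 70, range = NULL) {
  if (nbins < 2) stop("nbins must be at least 2")
  stopifnot(length(lfc_rna_prev) == length(lfc_rna_cur),
            length(lfc_ribo_prev) == length(lfc_ribo_cur))
  ok <- is.finite(lfc_rna_prev) & is.finite(lfc_ribo_prev) &
    is.finite(lfc_rna_cur) & is.finite(lfc_ribo_cur)
  edges <- grid_edges(lfc_rna_prev[ok], lfc_ribo_prev[ok], nbins, range)
  i <- bin_index(lfc_rna_prev, edges)
  j <- bin_index(lfc_ribo_prev, edges)
  inr <- ok & !is.na(i) & !is.na(j)
  key <- paste(i[inr], j[inr])
  drna <- tapply(lfc_rna_cur[inr] - lfc_rna_prev[inr], key, mean)
  dribo <- tapply(lfc_ribo_cur[inr] - lfc_ribo_prev[inr], key, mean)
  cnt <- tapply(key, key, length)
  ij <- do.call(rbind, strsplit(names(drna), " ", fixed = TRUE))
  out <- data.frame(bin_i = as.integer(ij[, 1]), bin_j = as.integer(ij[, 2]),
                    n = as.integer(cnt), d_rna = as.numeric(drna),
                    d_ribo = as.numeric(dribo))
  out$magnitude <- sqrt(out$d_rna^2 + out$d_ribo^2)
  out <- out[order(out$bin_i, out$bin_j), ]
  rownames(out) <- NULL
  attr(out, "edges") <- edges
  class(out) <- c("grid_summary", "data.frame")
  out
}
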