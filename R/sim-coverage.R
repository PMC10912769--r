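#' Simulate per-transcript coverage tracks with planted 5' onset drift
#'
#' Generates one coverage track per transcript per sample, in transcript
#' coordinates. The expected track is zero up to a 5' onset position, climbs
#' linearly over `ramp_width_nt` to the plateau depth, then stays flat to the
#' 3' end. In depleted samples the onset of a degraded gene
#' (`shift_sign = +1`) drifts 3'-ward by `shift_rate_nt_per_h * t`; a
#' stabilized gene (`shift_sign = -1`) drifts 5'-ward (clamped at position
#' 2). Control samples keep the baseline onset at every timepoint. Counts
#' carry independent Poisson noise per nucleotide unless `noise = FALSE`, in
#' which case the expected track is returned (useful for validating the
#' coverage-start detector against the planted geometry).
#'
#' @param truth a `sim_truth` object.
#' @param config the [sim_config()] used to build it.
#' @param noise logical; `FALSE` returns noise-free expected tracks.
#' @return an object of class `coverage_set`: list with `tracks` (per
#'   sample, a named list of numeric vectors over `[0, tx_len)`), `samples`
#'   (data frame: `sample_id`, `condition`, `timepoint_h`), and `onsets`
#'   (genes x samples matrix of planted onset positions).
#' @export
simulate_coverage <- function(truth, config, noise = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(config$seed + 2L)
  genes <- truth$genes
  n <- nrow(genes)
  tt <- truth$timepoints_h
  ramp <- config$ramp_width_nt
  if (any(genes$tx_len < max(config$onset_range_nt) + ramp + 10))
    stop("transcript(s) shorter than onset + ramp; increase coverage_len_range")

  onset0 <- round(stats::runif(n, config$onset_range_nt[1],
                               config$onset_range_nt[2]))

  samples <- expand.grid(timepoint_h = tt,
                         condition = c("ctrl", "depleted"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- with(samples, paste("cov", condition,
                                           paste0("t", timepoint_h), sep = "_"))

  expected_track <- function(L, onset, depth) {
    v <- numeric(L)
    ramp_idx <- seq_len(ramp) + onset
    ramp_idx <- ramp_idx[ramp_idx <= L]
    v[ramp_idx] <- depth * seq_along(ramp_idx) / ramp
    if (onset + ramp < L) v[(onset + ramp + 1):L] <- depth
    v
  }

  onsets <- matrix(NA_integer_, n, nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample_id))
  tracks <- vector("list", nrow(samples))
  names(tracks) <- samples$sample_id
  for (j in seq_len(nrow(samples))) {
    sj <- samples[j, ]
    shift <- if (sj$condition == "ctrl") rep(0, n)
             else genes$shift_sign * config$shift_rate_nt_per_h * sj$timepoint_h
    onset_j <- pmax(2L, pmin(round(onset0 + shift),
                             genes$tx_len - ramp - 5L))
    onsets[, j] <- onset_j
    tr <- lapply(seq_len(n), function(i) {
      mu <- expected_track(genes$tx_len[i], onset_j[i], config$coverage_depth)
      if (noise) as.numeric(stats::rpois(length(mu), mu)) else mu
    })
    names(tr) <- genes$gene_id
    tracks[[j]] <- tr
  }

  structure(list(tracks = tracks, samples = samples, onsets = onsets),
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat("coverage_set:", length(x$tracks[[1]]), "transcripts x",
      length(x$tracks), "samples\n")
  invisible(x)
}

#' Write coverage tracks as bedGraph files
#'
#' One 4-column bedGraph per sample (`<sample_id>.bedGraph`), in transcript
#' coordinates: each transcript is its own "chromosome" and intervals are
#' 0-based half-open, with runs of equal coverage collapsed.
#'
#' @param covset a `coverage_set`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_coverage <- function(covset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(covset$tracks)) {
    tr <- covset$tracks[[sid]]
    rows <- lapply(names(tr), function(tx) {
      r <- rle(tr[[tx]])
      e <- cumsum(r$lengths)
      s <- c(0L, e[-length(e)])
      keep <- r$values != 0
      if (!any(keep)) return(NULL)
      data.frame(chrom = tx, start = s[keep], end = e[keep],
                 value = r$values[keep], stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    utils::write.table(df, file.path(dir, paste0(sid, ".bedGraph")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(dir)
}

#' Read bedGraph coverage tracks written by [write_coverage()]
#'
#' @param dir directory of `<sample_id>.bedGraph` files.
#' @param samples sample sheet (`sample_id`, `condition`, `timepoint_h`); if
#'   `NULL`, reconstructed from the file names produced by the simulator.
#' @param tx_lengths named integer vector of transcript lengths, required to
#'   restore trailing zero-coverage stretches.
#' @return a `coverage_set`.
#' @export
read_coverage <- function(dir, tx_lengths, samples = NULL) {
  files <- list.files(dir, pattern = "\\.bedGraph$", full.names = TRUE)
  sids <- sub("\\.bedGraph$", "", basename(files))
  tracks <- lapply(files, function(f) {
    bg <- utils::read.table(f, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "value"),
                            stringsAsFactors = FALSE)
    tr <- lapply(names(tx_lengths), function(tx) {
      v <- numeric(tx_lengths[[tx]])
      sub <- bg[bg$chrom == tx, , drop = FALSE]
      for (k in seq_len(nrow(sub)))
        v[(sub$start[k] + 1):sub$end[k]] <- sub$value[k]
      v
    })
    names(tr) <- names(tx_lengths)
    tr
  })
  names(tracks) <- sids
  if (is.null(samples)) {
    parts <- strsplit(sids, "_", fixed = TRUE)
    samples <- data.frame(
      sample_id = sids,
      condition = vapply(parts, `[`, character(1), 2),
      timepoint_h = as.numeric(sub("^t", "",
                                   vapply(parts, `[`, character(1), 3))),
      stringsAsFactors = FALSE)
  }
  structure(list(tracks = tracks, samples = samples, onsets = NULL),
            class = "coverage_set")
}
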