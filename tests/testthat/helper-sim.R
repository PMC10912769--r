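# Small shared simulation used by several unit tests (kept tiny for speed).
tiny_config <- function(n_genes = 60, seed = 3, ...) {
  sim_config(n_genes = n_genes, seed = seed, ...)
}

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_config()
      cache <<- list(cfg = cfg, sim = simulate_transcriptome(cfg))
    }
    cache
  }
})

# write a GTF file from hand-specified feature rows
write_hand_gtf <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    paste(r$chrom, "test", r$type, r$start, r$end, ".", r$strand, ".",
          sprintf('gene_id "%s"; transcript_id "%s";', r$gene, r$tx),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

# exact one-sided rank-sum p-value by exhaustive enumeration (oracle)
enumerate_ranksum_p <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  if (alternative == "less") mean(stats <= r_obs) else mean(stats >= r_obs)
}
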