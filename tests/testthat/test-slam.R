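sam_line <- function(qname, rname, pos, cigar, seq, flag = 0L) {
  paste(qname, flag, rname, pos, 255L, cigar, "*", 0L, 0L, seq, "*",
        sep = "\t")
}

test_that("hand-built alignments are scanned base by base", {
  ref <- Biostrings::DNAStringSet(c(gp = "ATGTATGT", gm = "ATGTATGT"))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    sam_line("r1", "gp", 1, "4M", "ACGT"),   # ref T -> read C at pos 2: converted
    sam_line("r2", "gp", 1, "4M", "ATGT"),   # perfect match
    sam_line("r3", "gp", 5, "4M", "ATGA"),   # T>A mismatch only: not T>C
    sam_line("r4", "gm", 1, "4M", "GTGT"),   # A>G at pos 1: sense T>C on minus gene
    sam_line("r5", "gm", 1, "4M", "ACGT"),   # T>C on ref = sense A>G: ignored
    sam_line("r6", "gp", 1, "2S2M", "GGAT"), # soft clip consumed, match A,T
    sam_line("r7", "gp", 2, "2M2D2M", "TGTG"),  # deletion skips ref 4-5; ref 6-7 TG vs TG
    sam_line("r8", "gp", 1, "2M2I2M", "ATCCGT"), # insertion; matches ref 1-4
    sam_line("r9", "*", 0, "*", "AAAA", flag = 4L)  # unmapped: excluded
  ), sam)
  cc <- scan_tc_reads(sam, ref, gene_strand = c(gp = "+", gm = "-"))
  expect_equal(unname(cc$total[, 1]), c(6L, 2L))
  expect_equal(unname(cc$tc["gp", 1]), 1L)
  expect_equal(unname(cc$tc["gm", 1]), 1L)
  expect_equal(unname(cc$qc["excluded_reads"]), 1L)
})

test_that("a reference without T cannot yield converted reads on the plus strand", {
  ref <- Biostrings::DNAStringSet(c(g0 = "AGGCAGGC"))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(sam_line("r1", "g0", 1, "4M", "CCCC"),
               sam_line("r2", "g0", 1, "8M", "AGGCAGGC")), sam)
  cc <- scan_tc_reads(sam, ref)
  expect_equal(unname(cc$total[, 1]), 2L)
  expect_equal(unname(cc$tc[, 1]), 0L)
})

test_that("the scanner equals an independent brute-force scan on 200 reads", {
  set.seed(21)
  txs <- Biostrings::DNAStringSet(c(
    a = paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
    b = paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")))
  sam <- tempfile(fileext = ".sam")
  truth <- write_slam_sam(txs, sam, n_reads_per_tx = 100, seed = 22)
  cc <- scan_tc_reads(sam, txs)
  # brute force: substring comparison of every read against the reference
  fields <- strsplit(grep("^@", readLines(sam), value = TRUE,
                          invert = TRUE), "\t")
  brute_total <- c(a = 0L, b = 0L); brute_tc <- brute_total
  for (f in fields) {
    rn <- f[3]; pos <- as.integer(f[4]); seq <- f[10]
    refsub <- substring(as.character(txs[[rn]]), pos,
                        pos + nchar(seq) - 1L)
    rb <- strsplit(refsub, "")[[1]]; qb <- strsplit(seq, "")[[1]]
    brute_total[rn] <- brute_total[rn] + 1L
    if (any(rb == "T" & qb == "C")) brute_tc[rn] <- brute_tc[rn] + 1L
  }
  expect_equal(unname(cc$total[, 1]), unname(brute_total))
  expect_equal(unname(cc$tc[, 1]), unname(brute_tc))
  # and both equal the writer's own conversion truth
  expect_equal(unname(cc$tc[, 1]),
               as.vector(tapply(truth$converted, truth$rname, sum)))
})

test_that("conversion fractions are well-defined and bounded", {
  cc <- structure(list(
    total = matrix(c(20L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s")),
    tc = matrix(c(5L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s")),
    samples = data.frame(sample_id = "s")), class = "conversion_counts")
  fr <- tc_fraction(cc)
  expect_equal(fr["g1", "s"], 0.25)
  expect_true(is.na(fr["g2", "s"]))
})

test_that("zero conversion probability gives zero converted reads everywhere", {
  cfg <- tiny_config(n_genes = 20, seed = 13, conversion_prob = 0,
                     background_conversion = 0)
  sim <- simulate_transcriptome(cfg)
  slam <- simulate_slam(sim$truth, cfg)
  expect_true(all(slam$tc == 0))
})

test_that("higher conversion probability raises labeled conversion fractions", {
  means <- vapply(c(0.01, 0.03, 0.06), function(pc) {
    cfg <- tiny_config(n_genes = 80, seed = 14, conversion_prob = pc)
    sim <- simulate_transcriptome(cfg)
    slam <- simulate_slam(sim$truth, cfg)
    lab <- slam$samples$labeling == "4sU" & slam$samples$chase_time_h == 0
    mean(tc_fraction(slam)[, lab], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("label retention drops after the chase for any positive decay rate", {
  for (k in c(0.05, 0.12, 0.3)) {
    cfg <- tiny_config(n_genes = 60, seed = 15, decay_rate_per_h = k)
    sim <- simulate_transcriptome(cfg)
    slam <- simulate_slam(sim$truth, cfg)
    fr <- tc_fraction(slam)
    s <- slam$samples
    lab0 <- s$labeling == "4sU" & s$chase_time_h == 0
    lab8 <- s$labeling == "4sU" & s$chase_time_h == 8
    expect_lt(mean(fr[, lab8], na.rm = TRUE), mean(fr[, lab0], na.rm = TRUE))
  }
})

test_that("a gene with identical conversion counts in all samples gives p ~ 1", {
  samples <- expand.grid(replicate = 1:3, condition = c("ctrl", "depleted"),
                         labeling = c("4sU", "none"),
                         stringsAsFactors = FALSE)
  samples$chase_time_h <- 8
  samples$sample_id <- paste0("s", seq_len(nrow(samples)))
  n <- nrow(samples)
  cc <- structure(list(
    total = matrix(1000L, 2, n, dimnames = list(c("g1", "g2"),
                                                samples$sample_id)),
    tc = rbind(g1 = rep(40L, n),
               g2 = as.integer(rbinom(n, 1000, 0.04) + 1L)),
    samples = samples), class = "conversion_counts")
  st <- stability_test(cc)
  expect_gt(st$p[st$gene_id == "g1"], 0.999)
})

test_that("group fraction tests respect the intersection rule", {
  set.seed(16)
  frac <- setNames(c(rnorm(50, 0.10, 0.01), rnorm(50, 0.05, 0.01)),
                   paste0("g", 1:100))
  te_cls <- setNames(rep(c("TE_down", "NS"), each = 50), names(frac))
  st_cls <- setNames(rep(c("stabilized", "NS"), 50), names(frac))
  res <- group_fraction_test(frac, te_cls, alternative = "greater")
  expect_lt(res$p, 0.05)
  expect_equal(res$n_a + res$n_b, 100)
  res2 <- group_fraction_test(frac, te_cls, stability_class = st_cls,
                              alternative = "greater")
  expect_equal(res2$n_a + res2$n_b, 50)
  # identical distributions give a non-significant one-sided p
  frac_null <- setNames(rep(c(0.1, 0.2), 50), names(frac))
  expect_gt(group_fraction_test(frac_null, te_cls)$p, 0.2)
  empty_cls <- setNames(rep("NS", 100), names(frac))
  expect_warning(r3 <- group_fraction_test(frac, empty_cls), "empty")
  expect_true(is.na(r3$p))
})
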