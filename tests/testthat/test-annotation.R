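test_that("GTF coordinates convert to 0-based half-open transcript regions", {
  # single-exon plus-strand gene: exon 101-400, CDS 151-350 (1-based closed)
  gtf <- write_hand_gtf(tempfile(fileext = ".gtf"), list(
    list(chrom = "chr1", type = "exon", start = 101, end = 400,
         strand = "+", gene = "g1", tx = "t1"),
    list(chrom = "chr1", type = "CDS", start = 151, end = 350,
         strand = "+", gene = "g1", tx = "t1")))
  models <- suppressWarnings(read_annotation(gtf))  # 200-nt toy CDS
  m <- models[["t1"]]
  expect_equal(m$tx_len, 300L)
  expect_equal(unname(m$regions$utr5[1, ]), c(0L, 50L))
  expect_equal(unname(m$regions$cds[1, ]), c(50L, 250L))
  expect_equal(unname(m$regions$utr3[1, ]), c(250L, 300L))
})

test_that("minus-strand models reverse exon order and complement the sequence", {
  # 20-nt toy chromosome; transcript = two exons on the minus strand
  chrom <- Biostrings::DNAStringSet("AACCGGTTACGTACGTTTAA")
  names(chrom) <- "chrT"
  gtf <- write_hand_gtf(tempfile(fileext = ".gtf"), list(
    list(chrom = "chrT", type = "exon", start = 1, end = 8,
         strand = "-", gene = "gM", tx = "tM"),
    list(chrom = "chrT", type = "exon", start = 13, end = 20,
         strand = "-", gene = "gM", tx = "tM")))
  m <- read_annotation(gtf)[["tM"]]
  # sense transcript: revcomp(exon2) then revcomp(exon1)
  expected <- paste0(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString("ACGTTTAA"))),
    as.character(Biostrings::reverseComplement(Biostrings::DNAString("AACCGGTT"))))
  expect_equal(as.character(transcript_seq(m, chrom)), expected)
  # transcript position 0 is the genomic 3'-most base (position 20)
  expect_equal(genomic_to_tx(m, 20), 0L)
  expect_equal(genomic_to_tx(m, 13), 7L)
  expect_equal(genomic_to_tx(m, 8), 8L)
  expect_equal(tx_to_genomic(m, 0), 20L)
})

test_that("a GTF with no features yields an empty collection", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(character(0), gtf)
  expect_length(read_annotation(gtf), 0)
})

test_that("a CDS whose length is not a multiple of 3 is flagged", {
  gtf <- write_hand_gtf(tempfile(fileext = ".gtf"), list(
    list(chrom = "chr1", type = "exon", start = 1, end = 100,
         strand = "+", gene = "g1", tx = "t1"),
    list(chrom = "chr1", type = "CDS", start = 11, end = 30,
         strand = "+", gene = "g1", tx = "t1")))
  expect_warning(models <- read_annotation(gtf), "multiple of 3")
  expect_false(models[["t1"]]$cds_ok)
})

test_that("gc_content follows the ACGT-denominator definition", {
  expect_equal(gc_content("GCGC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ATGCN"), 0.5)  # N excluded
  expect_true(is.na(gc_content("")))
  expect_true(is.na(gc_content("NNN")))
})

test_that("codon frequencies exclude stops and sum to one", {
  cf <- codon_frequencies("ATGAAATAA")
  expect_equal(unname(cf["ATG"]), 0.5)
  expect_equal(unname(cf["AAA"]), 0.5)
  expect_equal(sum(cf), 1)
  expect_equal(unname(codon_frequencies("ATGATGATG")["ATG"]), 1.0)
  expect_warning(cf2 <- codon_frequencies("ATGTAAATG"), "internal stop")
  expect_equal(sum(cf2), 1)
  # any simulated CDS sums to 1
  sim <- tiny_sim()$sim
  m <- sim$models[[1]]
  cds <- region_seq(m, sim$transcripts[[m$gene_id]], "cds")
  expect_equal(sum(codon_frequencies(cds)), 1, tolerance = 1e-9)
})

test_that("GC by codon position splits the frame correctly", {
  expect_equal(unname(gc_by_codon_position("ATGGCA")), c(0.5, 0.5, 0.5))
  expect_equal(unname(gc_by_codon_position("GGGGGG")), c(1, 1, 1))
  expect_equal(unname(gc_by_codon_position("ATA")), c(0, 0, 0))
})

test_that("genomic/transcript coordinate conversion round-trips on both strands", {
  sim <- tiny_sim()$sim
  strands <- vapply(sim$models, `[[`, character(1), "strand")
  picks <- c(which(strands == "+")[1], which(strands == "-")[1])
  for (i in picks) {
    m <- sim$models[[i]]
    pos <- c(0L, 1L, m$tx_len %/% 2L, m$tx_len - 1L)
    expect_equal(genomic_to_tx(m, tx_to_genomic(m, pos)), pos,
                 label = m$transcript_id)
  }
})

test_that("region lengths partition the mature transcript for intronless genes", {
  sim <- tiny_sim()$sim
  for (m in sim$models) {
    if (length(m$introns)) next
    expect_equal(gcstab:::region_len(m, "utr5") + gcstab:::region_len(m, "cds") +
                   gcstab:::region_len(m, "utr3"), m$tx_len)
  }
})

test_that("simulator GTF round-trips through read_annotation", {
  cfg <- sim_config(n_genes = 12, seed = 5)
  sim <- simulate_transcriptome(cfg)
  d <- file.path(tempdir(), "rt")
  write_transcriptome(sim, d)
  genome <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  names(genome) <- sub(" .*", "", names(genome))
  models <- read_annotation(file.path(d, "annotation.gtf"))
  expect_setequal(names(models), names(sim$models))
  for (tid in names(models)) {
    s1 <- as.character(transcript_seq(models[[tid]], genome))
    gid <- models[[tid]]$gene_id
    expect_equal(s1, as.character(sim$transcripts[[gid]]), label = tid)
    expect_equal(models[[tid]]$cds_span, sim$models[[tid]]$cds_span,
                 label = tid)
  }
  unlink(d, recursive = TRUE)
})
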