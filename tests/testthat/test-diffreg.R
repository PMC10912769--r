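test_that("size factors follow the median-of-ratios convention", {
  m <- cbind(s1 = c(5L, 8L), s2 = c(5L, 8L))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(s1 = c(2, 4), s2 = c(4, 8))
  expect_equal(unname(size_factors(m2)), c(sqrt(0.5), sqrt(2)),
               tolerance = 1e-12)
  # equivariance: scaling one sample by 3 multiplies its factor by 3
  # (relative to the other sample's)
  m3 <- m2; m3[, 2] <- m3[, 2] * 3
  sf2 <- size_factors(m2); sf3 <- size_factors(m3)
  expect_equal(sf3[2] / sf3[1], 3 * sf2[2] / sf2[1], tolerance = 1e-12)
})

test_that("size factors fall back to totals when no gene is always nonzero", {
  m <- cbind(s1 = c(2L, 0L), s2 = c(0L, 8L))
  expect_warning(sf <- size_factors(m), "total-count")
  expect_equal(unname(sf), c(2, 8) / exp(mean(log(c(2, 8)))))
})

nb_design <- function(n_rep) {
  s <- expand.grid(replicate = seq_len(n_rep),
                   condition = c("ctrl", "depleted"),
                   assay = c("rna", "ribo"), stringsAsFactors = FALSE)
  s$sample_id <- paste0("s", seq_len(nrow(s)))
  s
}

test_that("a gene with identical counts in every sample gives p ~ 1", {
  s <- nb_design(3)
  counts <- rbind(g1 = rep(50L, nrow(s)),
                  g2 = as.integer(rpois(nrow(s), 80) + 1))
  res <- nb_lrt(counts, s, ~ assay + condition + assay:condition,
                ~ assay + condition, sf = rep(1, nrow(s)))
  expect_lt(res$deviance_diff[1], 1e-6)
  expect_gt(res$p_lrt[1], 0.999)
})

test_that("nb_lrt matches a Poisson GLM LRT oracle in the small-dispersion limit", {
  set.seed(42)
  s <- nb_design(3)
  n <- 50
  counts <- t(vapply(seq_len(n), function(g)
    as.integer(rpois(nrow(s), exp(rnorm(1, 5, 1)))), integer(nrow(s))))
  rownames(counts) <- paste0("g", seq_len(n))
  res <- nb_lrt(counts, s, ~ assay + condition + assay:condition,
                ~ assay + condition, sf = rep(1, nrow(s)),
                dispersions = 1e-8)
  oracle <- vapply(seq_len(n), function(g) {
    d <- cbind(s, y = counts[g, ])
    f1 <- glm(y ~ assay + condition + assay:condition, poisson(), data = d)
    f0 <- glm(y ~ assay + condition, poisson(), data = d)
    pchisq(f0$deviance - f1$deviance, df = 1, lower.tail = FALSE)
  }, numeric(1))
  expect_lt(max(abs(res$p_lrt - oracle)), 1e-3)
})

test_that("a planted interaction of 2 log2 units is detected with high power", {
  set.seed(7)
  s <- nb_design(3)
  n <- 100
  base <- 2^rnorm(n, 7, 1)
  mu <- outer(base, rep(1, nrow(s)))
  planted <- seq_len(n) <= 30  # a subset, so normalization stays estimable
  int <- s$assay == "ribo" & s$condition == "depleted"
  mu[planted, int] <- mu[planted, int] * 2^2
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.05), n,
                   dimnames = list(paste0("g", 1:n), s$sample_id))
  res <- nb_lrt(counts, s, ~ assay + condition + assay:condition,
                ~ assay + condition)
  expect_gt(mean(res$p_lrt[planted] < 0.05, na.rm = TRUE), 0.9)
})

test_that("te_test output satisfies its internal contracts", {
  st <- tiny_sim()
  cm <- simulate_counts(st$sim$truth, st$cfg)
  te <- te_test(cm, timepoints = 48)
  expect_equal(te$delta_te, te$lfc_ribo - te$lfc_rna)
  expect_true(all(te$padj >= te$p_lrt - 1e-12, na.rm = TRUE))
  called <- te$te_class != "NS"
  expect_true(all(te$padj[called] <= 0.05))
  mxy <- te$quadrant == "-xy"
  expect_true(all(sign(te$lfc_rna[mxy]) == -sign(te$lfc_ribo[mxy])))
  # BH monotonicity: padj non-decreasing in p rank
  o <- order(te$p_lrt)
  expect_true(all(diff(cummax(te$padj[o])) >= 0))
})

test_that("te_test agrees with DESeq2 on the same data", {
  st <- tiny_sim()
  cm <- simulate_counts(st$sim$truth, st$cfg)
  sel <- cm$samples$timepoint_h == 48
  te <- te_test(cm, timepoints = 48, refine_size_factors = FALSE)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cm$counts[te$gene_id, sel],
      S4Vectors::DataFrame(
        assay = factor(cm$samples$assay[sel], c("rna", "ribo")),
        condition = factor(cm$samples$condition[sel], c("ctrl", "depleted"))),
      design = ~ assay + condition + assay:condition)
    dds <- DESeq2::DESeq(dds, test = "LRT",
                         reduced = ~ assay + condition, quiet = TRUE)
    rr <- DESeq2::results(dds)
  })
  common <- !is.na(rr$pvalue) & !is.na(te$p_lrt)
  expect_gt(cor(-log10(te$p_lrt[common]), -log10(rr$pvalue[common]),
                method = "spearman"), 0.9)
  # significant calls largely coincide
  a <- te$padj <= 0.05; b <- rr$padj <= 0.05
  expect_gt(mean(a == b, na.rm = TRUE), 0.85)
})

test_that("single-assay input is rejected", {
  st <- tiny_sim()
  cm <- simulate_counts(st$sim$truth, st$cfg)
  sel <- cm$samples$assay == "rna"
  cm1 <- count_matrix(cm$counts[, sel], cm$samples[sel, ])
  expect_error(te_test(cm1), "both")
})

test_that("quadrant labels follow their definitions", {
  expect_equal(quadrant_classify(1, 1, 0.01, 0.8), "x")
  expect_equal(quadrant_classify(1, 1, 0.8, 0.01), "y")
  expect_equal(quadrant_classify(1, -1, 0.01, 0.01), "-xy")
  expect_equal(quadrant_classify(1, 1, 0.01, 0.01), "xy")
  expect_equal(quadrant_classify(1, 1, 0.2, 0.2), "ns")
})

test_that("gene-set selection is seeded, disjoint, and warns on short pools", {
  res <- data.frame(gene_id = paste0("g", 1:10),
                    lfc = c(2, 1.5, 1, 0.5, 0.2, -0.2, -0.5, -1, -1.5, -2),
                    p = c(0.001, 0.01, 0.5, 0.3, 0.6, 0.9, 0.25, 0.02,
                          0.005, 0.001))
  tpm <- setNames(rep(10, 10), res$gene_id)
  expect_warning(gs <- select_gene_sets(res, tpm, n_reg = 2, n_ctrl = 6,
                                        seed = 1),
                 "control")
  expect_equal(gs$stabilized, c("g1", "g2"))
  expect_equal(gs$degraded, c("g10", "g9"))
  expect_length(gs$control, 5)  # the whole p > 0.2 & TPM > 3 pool
  expect_length(intersect(gs$stabilized, gs$degraded), 0)
  expect_length(intersect(gs$control, c(gs$stabilized, gs$degraded)), 0)
  expect_warning(gs2 <- select_gene_sets(res, tpm, n_reg = 2, n_ctrl = 6,
                                         seed = 1))
  expect_identical(gs, gs2)
})
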