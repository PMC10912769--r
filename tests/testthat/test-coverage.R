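test_that("min/max normalization and its degenerate case behave", {
  expect_equal(normalize_track(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(normalize_track(c(0, 15, 30)), normalize_track(c(0, 5, 10)))
  expect_null(normalize_track(c(3, 3, 3)))
})

test_that("coverage start is the first threshold exceedance", {
  expect_equal(coverage_start(c(0, 0, 0.1, 0.5, 1.0)), 3L)
  expect_equal(coverage_start(c(1.0, 0.2, 0.9)), 0L)
  expect_true(is.na(coverage_start(c(0.1, 0.1, 0.1))))
  # translation equivariance: k prepended zeros shift the start by k
  v <- c(0, 0, 0.2, 0.6, 1)
  for (k in c(1, 3, 7))
    expect_equal(coverage_start(c(rep(0, k), v)), coverage_start(v) + k)
})

test_that("pooled starts interpolate between individual starts", {
  ramp <- function(onset, L = 200, depth = 50) {
    v <- numeric(L)
    v[(onset + 1):L] <- depth
    v
  }
  t1 <- ramp(10); t2 <- ramp(20)
  expect_equal(pooled_start(list(t1, t1, t1)), coverage_start(
    normalize_track(t1)))
  ps <- pooled_start(list(t1, t2))
  s1 <- coverage_start(normalize_track(t1))
  s2 <- coverage_start(normalize_track(t2))
  expect_gte(ps, min(s1, s2))
  expect_lte(ps, max(s1, s2))
  expect_equal(pooled_start(list(t2)), s2)
})

test_that("window fold changes behave at identity, doubling, and clipping", {
  L <- 600
  wt <- c(numeric(100), rep(10, L - 100)); wt[L] <- 100
  expect_equal(window_lfc(wt, wt, center = 150), 0)
  kd <- wt; kd[101:(L - 1)] <- 20
  # normalized by a shared max, the window ratio is 2; eps chosen negligible
  wtn <- wt / 100; kdn <- kd / 100
  expect_equal(window_lfc(kdn, wtn, center = 150, eps = 1e-4), 1,
               tolerance = 1e-2)
  # window wider than the transcript is clipped but still defined
  expect_equal(window_lfc(wtn, wtn, center = 10, width = 10 * L), 0)
})

test_that("time regression matches its closed forms", {
  tt <- c(0, 4, 8, 16, 24, 48)
  expect_equal(time_regression(tt / 48, tt, omit_intercept = TRUE), 1 / 48)
  expect_equal(time_regression(rep(3, 6), tt), 0)
  set.seed(1)
  for (r in 1:5) {
    y <- rnorm(6)
    expect_equal(time_regression(y, tt, omit_intercept = TRUE),
                 sum(tt * y) / sum(tt^2))
    expect_equal(time_regression(y, tt),
                 unname(coef(lm(y ~ tt))[2]))
  }
  expect_true(is.na(time_regression(c(1, 2, NA, NA, NA, NA), tt)))
})

test_that("two-condition deltas recover planted shifts", {
  ramp <- function(onset, L = 800, depth = 40) {
    v <- numeric(L)
    idx <- (onset + 1):(onset + 25)
    v[idx] <- depth * seq_along(idx) / 25
    v[(onset + 26):L] <- depth
    v
  }
  wt <- ramp(100)
  d0 <- two_condition_delta(list(wt), list(wt))
  expect_equal(d0$delta_start, 0)
  expect_equal(d0$delta_cov, 0)
  kd <- ramp(130)  # shifted 30 nt 3'-ward
  d1 <- two_condition_delta(list(kd), list(wt))
  expect_equal(d1$delta_start, 30)
})

test_that("rank-sum comparisons match exhaustive enumeration", {
  p <- compare_groups(c(1, 2, 3, 4, 5, 6),
                      c(rep("stabilized", 3), rep("control", 3)))
  expect_equal(unname(p["stabilized"]), 0.05)  # 1 / choose(6, 3)
  set.seed(8)
  for (r in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    for (alt in c("less", "greater")) {
      got <- compare_groups(c(x, y),
                            c(rep("stabilized", n1), rep("control", n2)),
                            direction = c(stabilized = alt,
                                          degraded = "greater"))
      expect_equal(unname(got["stabilized"]),
                   enumerate_ranksum_p(x, y, alt), tolerance = 1e-12)
    }
  }
  # identical groups sit near 0.5; tiny groups give NA
  pid <- suppressWarnings(  # ties force the normal approximation
    compare_groups(rep(1:4, 2),
                   c(rep("stabilized", 4), rep("control", 4))))
  expect_gt(unname(pid["stabilized"]), 0.3)
  pna <- compare_groups(c(1, 2, 3), c("stabilized", "control", "control"))
  expect_true(is.na(pna["stabilized"]))
})

test_that("bedGraph output round-trips through read_coverage", {
  cfg <- tiny_config(n_genes = 8, seed = 9)
  sim <- simulate_transcriptome(cfg)
  cov <- simulate_coverage(sim$truth, cfg)
  d <- file.path(tempdir(), "bg")
  write_coverage(cov, d)
  lens <- setNames(sim$truth$genes$tx_len, sim$truth$genes$gene_id)
  cov2 <- read_coverage(d, lens)
  for (sid in names(cov$tracks))
    for (tx in names(cov$tracks[[sid]]))
      expect_equal(cov2$tracks[[sid]][[tx]], cov$tracks[[sid]][[tx]],
                   label = paste(sid, tx))
  expect_equal(cov2$samples$timepoint_h[match(cov$samples$sample_id,
                                              cov2$samples$sample_id)],
               cov$samples$timepoint_h)
  unlink(d, recursive = TRUE)
})

test_that("noise-free tracks put the detected start on the planted onset", {
  cfg <- tiny_config(n_genes = 10, seed = 10, shift_rate_nt_per_h = 2)
  sim <- simulate_transcriptome(cfg)
  cov <- simulate_coverage(sim$truth, cfg, noise = FALSE)
  for (sid in names(cov$tracks)) {
    for (i in seq_len(5)) {
      tx <- names(cov$tracks[[sid]])[i]
      tr <- normalize_track(cov$tracks[[sid]][[tx]])
      got <- coverage_start(tr)
      planted <- cov$onsets[tx, sid]
      # first ramp step above 0.15 of plateau: within the ramp geometry
      expect_gte(got, planted)
      expect_lte(got, planted + cfg$ramp_width_nt * 0.2)
    }
  }
})

test_that("zero shift rate leaves depleted and control expectations identical", {
  cfg <- tiny_config(n_genes = 6, seed = 11, shift_rate_nt_per_h = 0)
  sim <- simulate_transcriptome(cfg)
  cov <- simulate_coverage(sim$truth, cfg, noise = FALSE)
  s <- cov$samples
  dep48 <- s$sample_id[s$condition == "depleted" & s$timepoint_h == 48]
  ctl48 <- s$sample_id[s$condition == "ctrl" & s$timepoint_h == 48]
  expect_identical(cov$tracks[[dep48]], cov$tracks[[ctl48]])
})

test_that("planted onset drift matches shift_rate x time by construction", {
  cfg <- tiny_config(n_genes = 30, seed = 12, shift_rate_nt_per_h = 2)
  sim <- simulate_transcriptome(cfg)
  cov <- simulate_coverage(sim$truth, cfg, noise = FALSE)
  s <- cov$samples
  dep24 <- s$sample_id[s$condition == "depleted" & s$timepoint_h == 24]
  ctl24 <- s$sample_id[s$condition == "ctrl" & s$timepoint_h == 24]
  degraded <- sim$truth$genes$gene_id[sim$truth$genes$class == "TE_up"]
  for (g in degraded)
    expect_equal(cov$onsets[g, dep24] - cov$onsets[g, ctl24], 48)
})
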