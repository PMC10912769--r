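synthetic_features <- function(n, p_noise = 9, seed = 1) {
  set.seed(seed)
  ft <- as.data.frame(matrix(rnorm(n * p_noise), n,
                             dimnames = list(paste0("g", seq_len(n)),
                                             paste0("noise", seq_len(p_noise)))))
  ft$GCcds <- runif(n, 0.3, 0.8)
  ft
}

test_that("a pure-noise target yields null held-out correlation", {
  ft <- synthetic_features(300, seed = 2)
  set.seed(3)
  target <- rnorm(300)
  fr <- fit_forest_cv(ft, target, seed = 4, ntree = 300)
  expect_lt(abs(mean(fr$per_fold$spearman)), 0.1)
})

test_that("a planted monotone GCcds signal is ranked first by the forest", {
  ft <- synthetic_features(300, seed = 5)
  set.seed(6)
  sig <- as.numeric(scale(ft$GCcds))
  target <- sig + rnorm(300)  # R^2 ~ 0.5
  fr <- fit_forest_cv(ft, target, seed = 7, ntree = 300)
  ranks <- vapply(paste0("fold", 1:5), function(cl)
    rank(-fr$importance[[cl]])[fr$importance$feature == "GCcds"], numeric(1))
  expect_gte(sum(ranks == 1), 4)
  expect_gt(mean(fr$per_fold$spearman), 0.5)
})

test_that("the lasso gives the planted feature the largest coefficient", {
  ft <- synthetic_features(300, seed = 8)
  set.seed(9)
  target <- as.numeric(scale(ft$GCcds)) + rnorm(300)
  la <- fit_lasso_cv(ft, target, seed = 10)
  expect_equal(la$importance$feature[which.max(abs(la$importance$importance))],
               "GCcds")
  expect_gt(mean(la$per_fold$spearman), 0.5)
})

test_that("lasso selection is invariant to pre-standardization feature scale", {
  ft <- synthetic_features(300, seed = 11)
  set.seed(12)
  target <- as.numeric(scale(ft$GCcds)) + rnorm(300)
  la1 <- fit_lasso_cv(ft, target, seed = 13)
  ft_scaled <- ft
  ft_scaled$GCcds <- ft_scaled$GCcds * 1000
  la2 <- fit_lasso_cv(ft_scaled, target, seed = 13)
  expect_equal(la1$importance$importance, la2$importance$importance,
               tolerance = 1e-6)
})

test_that("near-orthonormal design with one true coefficient selects that feature", {
  set.seed(14)
  n <- 200; p <- 8
  X <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # orthonormal columns
  ft <- as.data.frame(X)
  names(ft) <- paste0("f", seq_len(p))
  rownames(ft) <- paste0("g", seq_len(n))
  target <- 3 * ft$f3 + rnorm(n, 0, 0.3)
  la <- fit_lasso_cv(ft, target, seed = 15)
  imp <- la$importance
  expect_equal(imp$feature[which.max(imp$importance)], "f3")
  others <- imp$importance[imp$feature != "f3"]
  expect_true(all(others < 0.05 * max(imp$importance)))
})

test_that("duplicated features share importance without erasing the signal", {
  ft <- synthetic_features(300, seed = 16)
  set.seed(17)
  target <- as.numeric(scale(ft$GCcds)) + rnorm(300, 0, 0.7)
  fr1 <- fit_forest_cv(ft, target, seed = 18, ntree = 300)
  ft2 <- ft
  ft2$GCcds_copy <- ft2$GCcds
  fr2 <- fit_forest_cv(ft2, target, seed = 18, ntree = 300)
  i1 <- fr1$importance$importance[fr1$importance$feature == "GCcds"]
  dup <- fr2$importance$importance[
    fr2$importance$feature %in% c("GCcds", "GCcds_copy")]
  expect_true(all(dup > 0))
  expect_gt(sum(dup), 0.5 * i1)
  # the duplicated pair still dominates the noise features
  noise2 <- fr2$importance$importance[
    grepl("^noise", fr2$importance$feature)]
  expect_gt(max(dup), max(noise2))
})

test_that("fold assignment and reports are reproducible from the seed", {
  ft <- synthetic_features(200, seed = 19)
  set.seed(20)
  target <- as.numeric(scale(ft$GCcds)) + rnorm(200)
  fr1 <- fit_forest_cv(ft, target, seed = 21, ntree = 100)
  fr2 <- fit_forest_cv(ft, target, seed = 21, ntree = 100)
  expect_identical(fr1$folds, fr2$folds)
  expect_identical(fr1$importance, fr2$importance)
  expect_identical(fr1$per_fold, fr2$per_fold)
})

test_that("degenerate inputs are rejected or repaired", {
  ft <- synthetic_features(150, seed = 22)
  expect_error(fit_forest_cv(ft, rep(1, 150), seed = 1), "constant target")
  expect_error(fit_forest_cv(ft[1:50, ], rnorm(50), seed = 1), "at least")
  ft$dead <- 0
  set.seed(23)
  expect_warning(fit_lasso_cv(ft, rnorm(150) + ft$GCcds, seed = 1),
                 "constant feature")
})

test_that("rank_and_join binds reports and enforces a shared schema", {
  expect_equal(nrow(rank_and_join(list())), 0)
  ft <- synthetic_features(150, seed = 24)
  set.seed(25)
  target <- as.numeric(scale(ft$GCcds)) + rnorm(150)
  r1 <- fit_lasso_cv(ft, target, seed = 26)
  joined <- rank_and_join(list(a = r1, b = r1))
  expect_equal(joined[joined$dataset == "a", -1],
               joined[joined$dataset == "b", -1],
               ignore_attr = TRUE)
  expect_equal(joined$rank[joined$dataset == "a" & joined$feature == "GCcds"],
               1L)
  r2 <- r1
  r2$importance <- r2$importance[r2$importance$feature != "GCcds", ]
  expect_error(rank_and_join(list(a = r1, b = r2)), "schema")
})
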