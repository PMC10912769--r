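# Cross-validated interpretable regression: random forest with held-out
# permutation importance, and lasso on standardized features. All scaling
# and imputation statistics are computed on training folds only.

cv_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# median imputation using training-fold statistics
impute_median <- function(train, test) {
  med <- vapply(train, function(col) stats::median(col, na.rm = TRUE),
                numeric(1))
  med[is.na(med)] <- 0
  fill <- function(d) {
    for (j in seq_along(d)) d[[j]][is.na(d[[j]])] <- med[j]
    d
  }
  list(train = fill(train), test = fill(test))
}

# rank/linear correlation, NA (not a warning) for constant predictions
safe_cor <- function(pred, obs, method = "pearson") {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
  stats::cor(pred, obs, method = method)
}

new_importance_report <- function(model, per_fold, importance, seed, folds) {
  structure(list(model = model, per_fold = per_fold,
                 importance = importance, seed = seed, folds = folds),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("importance_report (", x$model, "): ", nrow(x$per_fold),
      " folds, mean held-out Spearman = ",
      round(mean(x$per_fold$spearman), 3), "\n", sep = "")
  top <- utils::head(x$importance[order(-abs(x$importance$importance)), ], 5)
  cat("top features:", paste(top$feature, collapse = ", "), "\n")
  invisible(x)
}

#' Random-forest regression with cross-validated permutation importance
#'
#' Fits a random-forest regression of a per-gene target (typically the
#' delta-TE, or the RNA log2 fold change in two-condition mode) on a feature
#' table, under k-fold cross-validation. Performance is the rank (Spearman)
#' correlation between predicted and observed values on the held-out fold;
#' importance is the permutation-based increase in held-out mean squared
#' error (the regression analog of mean decrease in accuracy), averaged over
#' folds. Missing feature values are imputed with training-fold medians.
#'
#' @param features data frame of numeric features (rownames = gene ids).
#' @param target numeric vector aligned to `features` rows; genes with
#'   missing target are dropped.
#' @param k number of folds.
#' @param seed seed controlling fold assignment, forest growth and
#'   permutations.
#' @param ntree trees per forest ([randomForest::randomForest] default).
#' @param n_perm permutations per feature and fold.
#' @return an `importance_report`: list with `model`, `per_fold`
#'   (fold, spearman, pearson), `importance` (feature, importance, and
#'   per-fold columns), `seed`, `folds`.
#' @export
fit_forest_cv <- function(features, target, k = 5, seed = 1L, ntree = 500,
                          n_perm = 3) {
  keep <- !is.na(target)
  features <- features[keep, , drop = FALSE]
  target <- target[keep]
  n <- nrow(features)
  if (n < 20 * k)
    stop("need at least ", 20 * k, " genes for ", k, "-fold cross-validation")
  if (stats::sd(target) == 0)
    stop("constant target: correlation is undefined")
  folds <- cv_folds(n, k, seed)

  per_fold <- data.frame(fold = seq_len(k), spearman = NA_real_,
                         pearson = NA_real_)
  imp <- matrix(NA_real_, ncol(features), k,
                dimnames = list(colnames(features), NULL))
  for (f in seq_len(k)) {
    tr <- folds != f
    dat <- impute_median(features[tr, , drop = FALSE],
                         features[!tr, , drop = FALSE])
    set.seed(seed + f)
    rf <- randomForest::randomForest(x = dat$train, y = target[tr],
                                     ntree = ntree)
    pred <- stats::predict(rf, dat$test)
    obs <- target[!tr]
    per_fold$spearman[f] <- safe_cor(pred, obs, method = "spearman")
    per_fold$pearson[f] <- safe_cor(pred, obs)
    mse0 <- mean((pred - obs)^2)
    for (j in seq_len(ncol(features))) {
      mses <- vapply(seq_len(n_perm), function(r) {
        d <- dat$test
        d[[j]] <- sample(d[[j]])
        mean((stats::predict(rf, d) - obs)^2)
      }, numeric(1))
      imp[j, f] <- mean(mses) - mse0
    }
  }
  importance <- data.frame(feature = colnames(features),
                           importance = rowMeans(imp),
                           stringsAsFactors = FALSE)
  importance <- cbind(importance,
                      stats::setNames(as.data.frame(imp),
                                      paste0("fold", seq_len(k))))
  new_importance_report("forest", per_fold, importance, seed, folds)
}

#' Lasso regression with nested cross-validation
#'
#' Outer k-fold cross-validation around [glmnet::cv.glmnet]: within each
#' training fold, features are standardized to zero mean and unit variance
#' (statistics from the training fold only), the penalty is chosen by inner
#' cross-validation, and the coefficients at the chosen penalty are
#' recorded. Importance is the mean absolute standardized coefficient
#' across outer folds (signed mean is kept alongside). All-zero-variance
#' feature columns are dropped with a warning.
#'
#' @inheritParams fit_forest_cv
#' @return an `importance_report` (importance = mean coefficient at the
#'   selected penalty; column `coef_mean` carries the signed mean).
#' @export
fit_lasso_cv <- function(features, target, k = 5, seed = 1L) {
  keep <- !is.na(target)
  features <- features[keep, , drop = FALSE]
  target <- target[keep]
  n <- nrow(features)
  if (n < 20 * k)
    stop("need at least ", 20 * k, " genes for ", k, "-fold cross-validation")
  if (stats::sd(target) == 0)
    stop("constant target: correlation is undefined")

  sds <- vapply(features, function(x) stats::sd(x, na.rm = TRUE), numeric(1))
  drop <- is.na(sds) | sds == 0
  if (any(drop)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(features)[drop], collapse = ", "))
    features <- features[, !drop, drop = FALSE]
  }
  folds <- cv_folds(n, k, seed)

  per_fold <- data.frame(fold = seq_len(k), spearman = NA_real_,
                         pearson = NA_real_)
  coefs <- matrix(NA_real_, ncol(features), k,
                  dimnames = list(colnames(features), NULL))
  for (f in seq_len(k)) {
    tr <- folds != f
    dat <- impute_median(features[tr, , drop = FALSE],
                         features[!tr, , drop = FALSE])
    mu <- colMeans(as.matrix(dat$train))
    sd_tr <- apply(as.matrix(dat$train), 2, stats::sd)
    sd_tr[sd_tr == 0] <- 1
    xs_tr <- scale(as.matrix(dat$train), center = mu, scale = sd_tr)
    xs_te <- scale(as.matrix(dat$test), center = mu, scale = sd_tr)
    set.seed(seed + f)
    cvfit <- glmnet::cv.glmnet(xs_tr, target[tr], alpha = 1,
                               standardize = FALSE, nfolds = 5)
    pred <- as.numeric(stats::predict(cvfit, xs_te, s = "lambda.min"))
    obs <- target[!tr]
    per_fold$spearman[f] <- safe_cor(pred, obs, method = "spearman")
    per_fold$pearson[f] <- safe_cor(pred, obs)
    cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[-1, 1]
    coefs[, f] <- cf[colnames(features)]
  }
  importance <- data.frame(feature = colnames(features),
                           importance = rowMeans(abs(coefs)),
                           coef_mean = rowMeans(coefs),
                           stringsAsFactors = FALSE)
  importance <- cbind(importance,
                      stats::setNames(as.data.frame(coefs),
                                      paste0("fold", seq_len(k))))
  new_importance_report("lasso", per_fold, importance, seed, folds)
}

#' Join importance reports across datasets
#'
#' Binds several `importance_report`s (sharing a feature schema) into one
#' long table of per-dataset model performance and per-feature importance,
#' the shape used to compare feature relevance across many knockdown
#' datasets.
#'
#' @param reports named list of `importance_report` objects.
#' @return data frame with columns `dataset`, `model`, `mean_spearman`,
#'   `feature`, `importance`, `rank` (1 = most important by absolute
#'   value); empty data frame for an empty list.
#' @export
rank_and_join <- function(reports) {
  if (!length(reports))
    return(data.frame(dataset = character(0), model = character(0),
                      mean_spearman = numeric(0), feature = character(0),
                      importance = numeric(0), rank = integer(0)))
  if (is.null(names(reports)))
    names(reports) <- paste0("dataset", seq_along(reports))
  schema <- reports[[1]]$importance$feature
  rows <- lapply(names(reports), function(nm) {
    rep <- reports[[nm]]
    missing <- setdiff(schema, rep$importance$feature)
    extra <- setdiff(rep$importance$feature, schema)
    if (length(missing) || length(extra))
      stop("feature schema mismatch in '", nm, "': missing [",
           paste(missing, collapse = ", "), "], extra [",
           paste(extra, collapse = ", "), "]")
    imp <- rep$importance[match(schema, rep$importance$feature), ]
    data.frame(dataset = nm, model = rep$model,
               mean_spearman = mean(rep$per_fold$spearman),
               feature = schema, importance = imp$importance,
               rank = rank(-abs(imp$importance), ties.method = "min"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
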