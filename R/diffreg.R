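# Negative-binomial GLM differential testing.
#
# The mean model is a log-link GLM with size factors as offsets. Dispersion
# (alpha; variance mu + alpha mu^2) is estimated by maximizing the
# Cox-Reid-adjusted likelihood profile under the full design: per gene when
# replication is generous, otherwise pooled within expression bins to form a
# mean-dispersion trend (per-gene MLEs at few residual df make the LRT
# anticonservative). The likelihood-ratio statistic between nested designs
# is referred to a chi-square distribution.

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median, over genes with nonzero
#' counts in every sample, of the ratio between the gene's count and its
#' geometric mean across samples, normalized to geometric mean 1. When no
#' gene is nonzero everywhere, falls back to total-count scaling with a
#' warning.
#'
#' @param counts genes x samples integer matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
#' @examples
#' m <- cbind(s1 = c(2, 4), s2 = c(4, 8))
#' size_factors(m)
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) {
    warning("no gene with nonzero counts in all samples; ",
            "falling back to total-count scaling")
    sf <- colSums(counts)
    if (any(sf == 0)) stop("sample with zero total counts")
    return(sf / exp(mean(log(sf))))
  }
  sub <- counts[keep, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geo, 2, stats::median)
  sf / exp(mean(log(sf)))
}

nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

# IRLS fit of the NB mean model at fixed dispersion
nb_fit <- function(y, X, offset, alpha) {
  fam <- MASS::negative.binomial(theta = 1 / alpha)
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = fam, offset = offset,
    control = list(maxit = 100, epsilon = 1e-8)))
  list(coef = fit$coefficients, mu = fit$fitted.values,
       ll = nb_loglik(y, fit$fitted.values, alpha),
       converged = isTRUE(fit$converged))
}

# Cox-Reid-adjusted profile log-likelihood of alpha
cr_profile_ll <- function(y, X, offset, alpha) {
  f <- nb_fit(y, X, offset, alpha)
  w <- f$mu / (1 + alpha * f$mu)
  xtwx <- crossprod(X * sqrt(w))
  ld <- determinant(xtwx, logarithm = TRUE)$modulus
  f$ll - 0.5 * as.numeric(ld)
}

estimate_dispersion_gene <- function(y, X, offset,
                                     interval = log(c(1e-6, 10))) {
  if (all(y == y[1])) return(1e-6)
  opt <- stats::optimize(function(la) cr_profile_ll(y, X, offset, exp(la)),
                         interval = interval, maximum = TRUE, tol = 0.05)
  exp(opt$maximum)
}

#' Estimate NB dispersions under a design
#'
#' For well-replicated designs (residual degrees of freedom of at least
#' `min_genewise_df`) each gene gets its own Cox-Reid-adjusted maximum
#' likelihood dispersion. For the small designs typical of a per-timepoint
#' comparison, per-gene MLEs are too noisy and make the likelihood-ratio
#' test anticonservative; genes are instead grouped into expression-level
#' bins and each bin's dispersion maximizes the pooled Cox-Reid-adjusted
#' profile likelihood over (a deterministic subsample of) its genes,
#' yielding a mean-dispersion trend that is interpolated on the log-mean
#' scale to give every gene its value.
#'
#' @param counts genes x samples integer matrix.
#' @param X full-model design matrix.
#' @param offset per-sample log size-factor offsets.
#' @param min_genewise_df residual df at or above which per-gene MLEs are
#'   used directly.
#' @param nbins maximum number of expression bins for the trend.
#' @param genes_per_bin genes per bin entering the pooled likelihood
#'   (evenly spaced by expression rank, so the result is deterministic).
#' @return numeric vector of dispersions (alpha), clamped to `[1e-8, 10]`.
#' @export
estimate_dispersions <- function(counts, X, offset, min_genewise_df = 20,
                                 nbins = 10, genes_per_bin = 75) {
  n <- nrow(counts)
  resid_df <- ncol(counts) - qr(X)$rank
  if (resid_df >= min_genewise_df) {
    raw <- vapply(seq_len(n), function(g)
      estimate_dispersion_gene(counts[g, ], X, offset), numeric(1))
    return(pmin(pmax(raw, 1e-8), 10))
  }
  base_mean <- rowMeans(sweep(counts, 2, exp(offset), `/`))
  usable <- which(base_mean > 0 &
                    apply(counts, 1, function(y) any(y != y[1])))
  if (length(usable) < 2) return(rep(1e-8, n))
  nb <- max(1L, min(nbins, length(usable) %/% 25L))
  lbm <- log(base_mean[usable])
  qs <- stats::quantile(lbm, probs = seq(0, 1, length.out = nb + 1))
  qs[1] <- qs[1] - 1e-9
  bin <- cut(lbm, unique(qs), labels = FALSE, include.lowest = TRUE)
  nb <- max(bin)
  centers <- alphas <- numeric(nb)
  for (b in seq_len(nb)) {
    gi <- usable[bin == b]
    centers[b] <- stats::median(log(base_mean[gi]))
    gi <- gi[order(base_mean[gi])]
    if (length(gi) > genes_per_bin)
      gi <- gi[round(seq(1, length(gi), length.out = genes_per_bin))]
    pooled <- function(la) sum(vapply(gi, function(g)
      cr_profile_ll(counts[g, ], X, offset, exp(la)), numeric(1)))
    alphas[b] <- stats::optimize(pooled, interval = log(c(1e-6, 10)),
                                 maximum = TRUE, tol = 0.02)$maximum
  }
  la <- if (nb == 1) rep(alphas, n)
  else stats::approx(centers, alphas, xout = log(pmax(base_mean, 1e-8)),
                     rule = 2)$y
  pmin(pmax(exp(la), 1e-8), 10)
}

#' Gene-wise likelihood-ratio test between nested NB GLMs
#'
#' Fits the full and reduced log-link negative-binomial models per gene
#' (size factors as offsets, dispersion shared between the two fits) and
#' tests `2 * (loglik_full - loglik_reduced)` against a chi-square with
#' degrees of freedom equal to the difference in parameter count.
#'
#' @param counts genes x samples integer matrix.
#' @param samples data frame of per-sample covariates.
#' @param full,reduced model formulas over columns of `samples`; `reduced`
#'   must be nested in `full`.
#' @param sf size factors; computed by [size_factors()] when `NULL`.
#' @param dispersions optional per-gene dispersion overrides (recycled);
#'   estimated by [estimate_dispersions()] when `NULL`.
#' @param min_genewise_df passed to [estimate_dispersions()].
#' @return data frame with one row per gene: `gene_id`, `base_mean`,
#'   `dispersion`, `deviance_diff`, `df`, `p_lrt`, `converged`. The full
#'   model's coefficient matrix (genes x coefficients, natural-log scale) is
#'   attached as attribute `"coefficients"`.
#' @export
nb_lrt <- function(counts, samples, full, reduced, sf = NULL,
                   dispersions = NULL, min_genewise_df = 20) {
  counts <- as.matrix(counts)
  stopifnot(nrow(samples) == ncol(counts))
  X_full <- stats::model.matrix(full, data = samples)
  X_red <- stats::model.matrix(reduced, data = samples)
  if (qr(X_red)$rank >= qr(X_full)$rank)
    stop("reduced design is not nested below the full design")
  if (is.null(sf)) sf <- size_factors(counts)
  offset <- log(sf)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, X_full, offset,
                                        min_genewise_df = min_genewise_df)
  dispersions <- rep_len(dispersions, nrow(counts))
  df <- qr(X_full)$rank - qr(X_red)$rank

  n <- nrow(counts)
  dev <- p <- rep(NA_real_, n)
  conv <- rep(FALSE, n)
  coefs <- matrix(NA_real_, n, ncol(X_full),
                  dimnames = list(rownames(counts), colnames(X_full)))
  for (g in seq_len(n)) {
    y <- counts[g, ]
    ff <- nb_fit(y, X_full, offset, dispersions[g])
    fr <- nb_fit(y, X_red, offset, dispersions[g])
    if (!ff$converged || !fr$converged) {
      # retry from scratch with more damping via a larger dispersion floor
      ff <- nb_fit(y, X_full, offset, max(dispersions[g], 1e-4))
      fr <- nb_fit(y, X_red, offset, max(dispersions[g], 1e-4))
    }
    if (ff$converged && fr$converged) {
      dev[g] <- max(2 * (ff$ll - fr$ll), 0)
      p[g] <- stats::pchisq(dev[g], df = df, lower.tail = FALSE)
      conv[g] <- TRUE
      coefs[g, ] <- ff$coef
    }
  }
  out <- data.frame(
    gene_id = if (!is.null(rownames(counts))) rownames(counts)
              else as.character(seq_len(n)),
    base_mean = rowMeans(sweep(counts, 2, sf, `/`)),
    dispersion = dispersions, deviance_diff = dev, df = df, p_lrt = p,
    converged = conv, stringsAsFactors = FALSE)
  attr(out, "coefficients") <- coefs
  out
}

#' Differential translation-efficiency test
#'
#' For each requested timepoint, tests depleted-versus-control changes in
#' translation efficiency by comparing a full NB GLM
#' `~ assay + condition + assay:condition` against a reduced model without
#' the assay:condition interaction (i.e. assuming no condition-dependent
#' difference between RNA-seq and Ribo-seq counts). Per-assay fold changes
#' and significances come from within-assay `~ condition` versus `~ 1`
#' tests. P-values are Benjamini-Hochberg adjusted per timepoint; a gene is
#' classed `TE_down`/`TE_up` by the sign of the interaction coefficient at
#' `padj <= alpha`, and placed in a fold-change quadrant by
#' [quadrant_classify()].
#'
#' @param cm a [count_matrix()] with both assays and both conditions.
#' @param timepoints timepoints (hours) to test; default all perturbed
#'   (nonzero) timepoints present.
#' @param alpha FDR threshold for the TE classes and quadrants.
#' @param reduced_drops_main_effect if `TRUE`, the reduced model drops the
#'   assay main effect as well (`~ condition`), the literal reading of
#'   "a reduced model without the assay type covariate"; the default drops
#'   only the interaction, the standard TE-testing design.
#' @param min_total_count genes with fewer summed counts at a timepoint are
#'   dropped from that timepoint's test.
#' @param refine_size_factors when `TRUE` (default), size factors are
#'   re-estimated after a first test pass using only genes not called
#'   regulated at a lenient cutoff (`padj >= 0.1`), and the test is rerun.
#'   With widespread asymmetric regulation the median-of-ratios factors are
#'   otherwise pulled by the regulated genes, which inflates the false
#'   discovery rate among unchanged genes.
#' @param min_genewise_df passed to [estimate_dispersions()].
#' @return data frame of class `te_results`: one row per gene and timepoint
#'   with `gene_id`, `timepoint_h`, `base_mean`, `lfc_rna`, `lfc_ribo`,
#'   `delta_te = lfc_ribo - lfc_rna`, `p_lrt`, `padj`, `p_rna`, `padj_rna`,
#'   `p_ribo`, `padj_ribo`, `te_class` and `quadrant`.
#' @export
te_test <- function(cm, timepoints = NULL, alpha = 0.05,
                    reduced_drops_main_effect = FALSE,
                    min_total_count = 10, refine_size_factors = TRUE,
                    min_genewise_df = 20) {
  stopifnot(inherits(cm, "count_matrix"))
  samples <- cm$samples
  if (length(unique(samples$assay)) < 2)
    stop("te_test needs both rna and ribo assays")
  if (is.null(timepoints))
    timepoints <- sort(setdiff(unique(samples$timepoint_h), 0))
  full <- ~ assay + condition + assay:condition
  reduced <- if (reduced_drops_main_effect) ~ condition else ~ assay + condition

  res <- lapply(timepoints, function(tp) {
    sel <- samples$timepoint_h == tp
    ss <- samples[sel, , drop = FALSE]
    ss$assay <- factor(ss$assay, levels = c("rna", "ribo"))
    ss$condition <- factor(ss$condition, levels = c("ctrl", "depleted"))
    counts <- cm$counts[, sel, drop = FALSE]
    keep <- rowSums(counts) >= min_total_count
    if (!all(keep))
      message(sum(!keep), " gene(s) below ", min_total_count,
              " total counts dropped at t=", tp)
    counts <- counts[keep, , drop = FALSE]

    run_pass <- function(sf) {
      lrt <- nb_lrt(counts, ss, full, reduced, sf = sf,
                    min_genewise_df = min_genewise_df)
      per_assay <- lapply(c(rna = "rna", ribo = "ribo"), function(a) {
        sel_a <- ss$assay == a
        lr <- nb_lrt(counts[, sel_a, drop = FALSE],
                     ss[sel_a, , drop = FALSE],
                     ~ condition, ~ 1, sf = sf[sel_a],
                     min_genewise_df = min_genewise_df)
        list(lfc = attr(lr, "coefficients")[, "conditiondepleted"] / log(2),
             p = lr$p_lrt)
      })
      list(lrt = lrt, per_assay = per_assay)
    }

    sf <- size_factors(counts)
    pass <- run_pass(sf)
    if (refine_size_factors) {
      padj1 <- stats::p.adjust(pass$lrt$p_lrt, method = "BH")
      padj1_rna <- stats::p.adjust(pass$per_assay$rna$p, method = "BH")
      padj1_ribo <- stats::p.adjust(pass$per_assay$ribo$p, method = "BH")
      unreg <- !is.na(padj1) & padj1 >= 0.1 &
        (is.na(padj1_rna) | padj1_rna >= 0.1) &
        (is.na(padj1_ribo) | padj1_ribo >= 0.1)
      if (sum(unreg) >= 50 && any(!unreg)) {
        sf <- tryCatch(size_factors(counts[unreg, , drop = FALSE]),
                       warning = function(w) sf)
        pass <- run_pass(sf)
      }
    }
    lrt <- pass$lrt
    per_assay <- pass$per_assay
    beta_int <- attr(lrt, "coefficients")[, "assayribo:conditiondepleted"]

    padj <- stats::p.adjust(lrt$p_lrt, method = "BH")
    padj_rna <- stats::p.adjust(per_assay$rna$p, method = "BH")
    padj_ribo <- stats::p.adjust(per_assay$ribo$p, method = "BH")
    te_class <- ifelse(!is.na(padj) & padj <= alpha,
                       ifelse(beta_int < 0, "TE_down", "TE_up"), "NS")
    out <- data.frame(
      gene_id = lrt$gene_id, timepoint_h = tp, base_mean = lrt$base_mean,
      lfc_rna = per_assay$rna$lfc, lfc_ribo = per_assay$ribo$lfc,
      delta_te = per_assay$ribo$lfc - per_assay$rna$lfc,
      p_lrt = lrt$p_lrt, padj = padj,
      p_rna = per_assay$rna$p, padj_rna = padj_rna,
      p_ribo = per_assay$ribo$p, padj_ribo = padj_ribo,
      te_class = te_class, stringsAsFactors = FALSE)
    out$quadrant <- quadrant_classify(out$lfc_rna, out$lfc_ribo,
                                      out$padj_rna, out$padj_ribo,
                                      alpha = alpha)
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("te_results", "data.frame")
  out
}

#' Quadrant classification on the Ribo-seq/RNA-seq fold-change plane
#'
#' Labels each gene by where it sits in the two-assay coordinate system:
#' `x` = significant in RNA-seq only, `y` = significant in Ribo-seq only,
#' `xy` = significant in both with concordant fold-change signs, `-xy` =
#' significant in both with opposite signs, `ns` otherwise.
#'
#' @param lfc_rna,lfc_ribo per-assay log2 fold changes.
#' @param padj_rna,padj_ribo per-assay adjusted p-values.
#' @param alpha significance threshold.
#' @return character vector of quadrant labels.
#' @export
quadrant_classify <- function(lfc_rna, lfc_ribo, padj_rna, padj_ribo,
                              alpha = 0.05) {
  sig_rna <- !is.na(padj_rna) & padj_rna <= alpha
  sig_ribo <- !is.na(padj_ribo) & padj_ribo <= alpha
  out <- rep("ns", length(lfc_rna))
  out[sig_rna & !sig_ribo] <- "x"
  out[!sig_rna & sig_ribo] <- "y"
  both <- sig_rna & sig_ribo
  same <- sign(lfc_rna) == sign(lfc_ribo)
  out[both & same] <- "xy"
  out[both & !same] <- "-xy"
  out
}

#' Select stabilized, degraded and control gene sets
#'
#' Ranks an RNA-seq differential result by p-value and takes the `n_reg`
#' most stabilized (positive fold change) and `n_reg` most degraded
#' (negative fold change) genes; `n_ctrl` control genes are sampled, with a
#' fixed seed, from non-regulated genes with `p > 0.2` and `TPM > 3`. The
#' three sets are disjoint.
#'
#' @param rna_results data frame with columns `gene_id`, `lfc`, `p`.
#' @param tpm named vector of TPM values (names = gene ids).
#' @param n_reg regulated-set size (each of stabilized and degraded).
#' @param n_ctrl control-set size.
#' @param seed seed for the control sample.
#' @return list with character vectors `stabilized`, `degraded`, `control`.
#' @export
select_gene_sets <- function(rna_results, tpm, n_reg = 250, n_ctrl = 1500,
                             seed = 1L) {
  stopifnot(all(c("gene_id", "lfc", "p") %in% names(rna_results)))
  r <- rna_results[!is.na(rna_results$p), , drop = FALSE]
  up <- r[r$lfc > 0, , drop = FALSE]
  dn <- r[r$lfc < 0, , drop = FALSE]
  take <- function(d, n, what) {
    if (nrow(d) < n)
      warning("only ", nrow(d), " eligible ", what, " genes (requested ",
              n, ")")
    d$gene_id[order(d$p)][seq_len(min(n, nrow(d)))]
  }
  stabilized <- take(up, n_reg, "stabilized")
  degraded <- take(dn, n_reg, "degraded")
  pool <- r$gene_id[r$p > 0.2 & !is.na(tpm[r$gene_id]) & tpm[r$gene_id] > 3]
  pool <- setdiff(pool, c(stabilized, degraded))
  if (length(pool) < n_ctrl)
    warning("only ", length(pool), " eligible control genes (requested ",
            n_ctrl, ")")
  set.seed(seed)
  control <- sort(sample(pool, min(n_ctrl, length(pool))))
  list(stabilized = stabilized, degraded = degraded, control = control)
}

#' TPM from a count matrix
#'
#' Transcripts-per-million from size-factor-normalized counts and effective
#' (exonic) lengths, averaged over the selected samples.
#'
#' @param cm a [count_matrix()].
#' @param lengths named vector of exonic transcript lengths.
#' @param which logical or integer index of samples to average over;
#'   default: control RNA-seq samples.
#' @return named numeric vector of TPM values.
#' @export
compute_tpm <- function(cm, lengths, which = NULL) {
  if (is.null(which))
    which <- cm$samples$assay == "rna" & cm$samples$condition == "ctrl"
  counts <- cm$counts[, which, drop = FALSE]
  sf <- size_factors(cm$counts)[which]
  norm <- sweep(counts, 2, sf, `/`)
  m <- rowMeans(norm)
  len <- lengths[rownames(counts)]
  rate <- m / len
  1e6 * rate / sum(rate, na.rm = TRUE)
}
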