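#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-data generators. The
#' defaults describe a degron-style depletion time course sampled at
#' 0/4/8/16/24/48 h with timepoint-matched controls, in which a configurable
#' fraction of genes is translationally suppressed (`TE_down`: ribosome
#' occupancy drops early, mRNA abundance rises late, i.e. stabilization of
#' untranslated transcripts) or the mirror image (`TE_up`). The magnitude of
#' the planted effect scales with the gene's coding-sequence GC content
#' (GCcds), so GCcds is the ground-truth driver that the feature-importance
#' stage is expected to recover.
#'
#' @param n_genes number of genes to simulate.
#' @param timepoints_h sampling times in hours; the first must be 0.
#' @param n_replicates replicates per (assay, condition, timepoint) cell.
#' @param frac_te_down,frac_te_up fractions of genes planted as `TE_down`
#'   (translationally suppressed, later stabilized) and `TE_up`; the
#'   remainder are `unchanging`.
#' @param gc_range range of target coding-sequence GC fractions.
#' @param gc_effect_direction `+1` (default): higher GCcds gives a stronger
#'   effect; `-1` reverses the relationship (used to check that the
#'   importance stage is sign-agnostic).
#' @param effect_size_lfc maximum absolute per-assay log2 fold change; a
#'   gene's own effect is `effect_size_lfc` scaled by its GC weight (see
#'   Details).
#' @param dispersion negative-binomial dispersion alpha, i.e. the reciprocal
#'   of the `size` parameter of [stats::rnbinom()]; variance is
#'   `mu + alpha * mu^2`.
#' @param mean_expression_log_mu,mean_expression_log_sd mean and sd of
#'   baseline expression on the log2 scale.
#' @param coverage_len_range range of simulated transcript lengths (nt) used
#'   by the coverage generator.
#' @param shift_rate_nt_per_h drift of the 5' coverage onset, in nt per hour,
#'   for degraded genes (3'-ward) and stabilized genes (5'-ward) in depleted
#'   samples.
#' @param conversion_prob per-T probability that a reference T is read as C
#'   in a labeled, still-labeled read.
#' @param background_conversion per-read probability of a spurious T>C call
#'   in unlabeled (or label-lost) reads.
#' @param label_efficiency fraction of molecules carrying label at chase
#'   time 0.
#' @param decay_rate_per_h baseline mRNA decay rate k (1/h) governing
#'   post-chase label loss, `exp(-k t)`.
#' @param stabilization_factor,destabilization_factor multipliers applied to
#'   `decay_rate_per_h` for stabilized (`TE_down`) and degraded (`TE_up`)
#'   genes in depleted samples.
#' @param coverage_depth expected plateau read depth of a coverage track.
#' @param ramp_width_nt width of the linear 5' ramp from zero coverage to
#'   plateau.
#' @param onset_range_nt range of baseline 5' coverage-onset positions.
#' @param reads_per_gene_slam expected total read count per gene and sample
#'   in the SLAM-seq generator.
#' @param ts_per_read expected number of reference T positions covered by
#'   one read (binomial size for per-read conversion chances).
#' @param seed integer seed; identical configurations (including seed)
#'   reproduce identical outputs byte for byte.
#'
#' @details The per-gene effect weight is
#' `w = 0.5 + 0.5 * (gc - lo) / (hi - lo)` for `gc_effect_direction = +1`
#' (mirrored for `-1`), so even the weakest regulated gene carries half the
#' maximal effect and the planted log2 fold change is a monotone, affine
#' function of GCcds. Ribo-seq effects reach full size by the second
#' perturbed timepoint; RNA-seq effects ramp linearly and reach full size at
#' the last timepoint, reproducing the early-translation/late-abundance
#' ordering of the degron response.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_transcriptome()], [simulate_counts()],
#'   [simulate_coverage()], [simulate_slam()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 7)
#' cfg$timepoints_h
sim_config <- function(n_genes = 1000,
                       timepoints_h = c(0, 4, 8, 16, 24, 48),
                       n_replicates = 4,
                       frac_te_down = 0.30,
                       frac_te_up = 0.15,
                       gc_range = c(0.30, 0.80),
                       gc_effect_direction = 1,
                       effect_size_lfc = 1.5,
                       dispersion = 0.05,
                       mean_expression_log_mu = 7,
                       mean_expression_log_sd = 1.5,
                       coverage_len_range = c(600, 1200),
                       shift_rate_nt_per_h = 2,
                       conversion_prob = 0.02,
                       background_conversion = 0.001,
                       label_efficiency = 0.8,
                       decay_rate_per_h = 0.12,
                       stabilization_factor = 0.3,
                       destabilization_factor = 2,
                       coverage_depth = 30,
                       ramp_width_nt = 25,
                       onset_range_nt = c(110, 160),
                       reads_per_gene_slam = 400,
                       ts_per_read = 10,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), timepoints_h = as.numeric(timepoints_h),
    n_replicates = as.integer(n_replicates),
    frac_te_down = frac_te_down, frac_te_up = frac_te_up,
    gc_range = as.numeric(gc_range),
    gc_effect_direction = gc_effect_direction,
    effect_size_lfc = effect_size_lfc, dispersion = dispersion,
    mean_expression_log_mu = mean_expression_log_mu,
    mean_expression_log_sd = mean_expression_log_sd,
    coverage_len_range = as.integer(coverage_len_range),
    shift_rate_nt_per_h = shift_rate_nt_per_h,
    conversion_prob = conversion_prob,
    background_conversion = background_conversion,
    label_efficiency = label_efficiency,
    decay_rate_per_h = decay_rate_per_h,
    stabilization_factor = stabilization_factor,
    destabilization_factor = destabilization_factor,
    coverage_depth = coverage_depth,
    ramp_width_nt = as.integer(ramp_width_nt),
    onset_range_nt = as.numeric(onset_range_nt),
    reads_per_gene_slam = reads_per_gene_slam,
    ts_per_read = as.integer(ts_per_read),
    seed = as.integer(seed))

  stopifnot(cfg$n_genes >= 1, cfg$n_replicates >= 1)
  if (cfg$timepoints_h[1] != 0 || any(cfg$timepoints_h < 0) ||
      is.unsorted(cfg$timepoints_h, strictly = TRUE))
    stop("timepoints_h must start at 0 and increase strictly")
  if (cfg$frac_te_down < 0 || cfg$frac_te_up < 0 ||
      cfg$frac_te_down + cfg$frac_te_up > 1)
    stop("frac_te_down + frac_te_up must lie in [0, 1]")
  if (length(cfg$gc_range) != 2 || any(cfg$gc_range < 0 | cfg$gc_range > 1) ||
      cfg$gc_range[1] > cfg$gc_range[2])
    stop("gc_range must be an increasing pair within [0, 1]")
  if (!cfg$gc_effect_direction %in% c(-1, 1))
    stop("gc_effect_direction must be +1 or -1")
  stopifnot(cfg$effect_size_lfc >= 0, cfg$dispersion > 0,
            all(is.finite(unlist(cfg[vapply(cfg, is.numeric, TRUE)]))),
            cfg$conversion_prob >= 0, cfg$conversion_prob <= 1,
            cfg$coverage_len_range[1] > 0,
            cfg$coverage_len_range[1] <= cfg$coverage_len_range[2])
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes;",
      length(x$timepoints_h), "timepoints (",
      paste(x$timepoints_h, collapse = "/"), "h);",
      x$n_replicates, "replicates\n")
  cat("  planted fractions: TE_down", x$frac_te_down,
      "TE_up", x$frac_te_up, "\n")
  cat("  GCcds range", paste(x$gc_range, collapse = "-"),
      "effect direction", x$gc_effect_direction,
      "max |lfc|", x$effect_size_lfc, "\n")
  cat("  seed", x$seed, "\n")
  invisible(x)
}

# GC -> effect weight in [0.5, 1]; monotone increasing for direction +1.
gc_effect_weight <- function(gc, config) {
  lo <- config$gc_range[1]; hi <- config$gc_range[2]
  r <- if (hi > lo) (gc - lo) / (hi - lo) else rep(0.5, length(gc))
  r <- pmin(pmax(r, 0), 1)
  if (config$gc_effect_direction < 0) r <- 1 - r
  0.5 + 0.5 * r
}

# Time profiles of the planted per-assay log2 fold changes (depleted vs ctrl).
# Ribo reaches full size at the second perturbed timepoint; RNA ramps linearly
# to full size at the last timepoint. Signs: TE_down = ribo down / rna up.
trajectory_profiles <- function(timepoints_h) {
  tt <- timepoints_h
  t_full_ribo <- if (length(tt) >= 3) tt[3] else tt[length(tt)]
  list(ribo = pmin(tt / t_full_ribo, 1),
       rna = tt / tt[length(tt)])
}
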