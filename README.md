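# gcstab

Analysis toolkit for a recurring phenotype in post-transcriptional
regulation: when a translation-promoting RNA helicase is acutely depleted,
translationally suppressed mRNAs escape 5′→3′ decay and accumulate, and the
feature that best predicts this stabilization is the **GC content of the
coding sequence (GCcds)**. `gcstab` is aimed at computational biologists
working with paired Ribo-seq/RNA-seq time courses, SLAM-seq labeling
experiments, and per-transcript coverage tracks who want to detect, rank
and validate sequence features behind such regulation.

## What it computes

**Differential translation efficiency.** Counts for gene *g* in sample *j*
are modelled as NB(*s*<sub>j</sub>*q*<sub>gj</sub>, α) with log-link design
`~ assay + condition + assay:condition` and median-of-ratios size factors
as offsets. Translation-efficiency (TE) regulation is a likelihood-ratio
test of the assay-by-condition interaction against the reduced model
without it (Δ-TE = log2FC<sub>Ribo</sub> − log2FC<sub>RNA</sub>), with
Benjamini–Hochberg control at FDR 0.05 and a quadrant classification
(`x`, `y`, `xy`, `-xy`, `ns`) on the two-assay fold-change plane.
Dispersions maximize the Cox–Reid-adjusted profile likelihood, pooled
across expression bins for modestly replicated designs.

**Feature importance.** A per-gene feature ledger (GC content by region and
codon position, 61 codon frequencies, lengths, read densities, baseline TE
and intron/exon maturity) feeds 5-fold cross-validated random-forest and
lasso regressions. Importance is permutation increase in held-out MSE
(mean-decrease-in-accuracy analog) for the forest and coefficients at the
inner-CV-selected penalty for the lasso; performance is held-out Spearman
correlation.

**5′-coverage-shift statistic.** Per transcript, min/max-normalized
coverage crosses 0.15 at the "coverage start"; a 250-nt window around the
pooled-sample start summarizes 5′ coverage. Over a depletion time course,
the slope of start positions on time (`beta_start`, intercept kept) and the
slope of window log2 fold changes versus timepoint-matched controls
(`beta_cov`, no intercept: Σty/Σt²) quantify 5′→3′ decay; one-sided
Wilcoxon rank-sum tests compare the top-250 stabilized and degraded genes
against 1500 controls. A 3′-anchored run of the identical machinery is the
built-in negative control.

**SLAM-seq analytics.** A minimal SAM scanner counts reads with ≥1
sense-strand T>C mismatch against the reference; the stability test is an
NB GLM of converted-read counts on `~ labeling + depletion` versus
`~ labeling`, with size factors from total reads so the depletion term
measures conversion enrichment, not expression.

**Grid summaries.** 70×70 binning of the fold-change plane: per-cell means
(e.g. GCcds) and mean displacement vectors between consecutive timepoints.

**Synthetic data with planted truth.** `sim_config()` +
`simulate_transcriptome()/simulate_counts()/simulate_coverage()/simulate_slam()`
generate a toy transcriptome (GTF/FASTA/bedGraph/TSV writers included)
whose regulation classes, GC-dependent effect sizes, coverage-onset drifts
and label-decay rates are known, so every estimator above can be scored
against ground truth.

## Worked example

```r
library(gcstab)
report <- run_demo(seed = 113)
report
```

```
gcstab demo report (seed 113)
  TE test: sensitivity 0.996, empirical FDR 0.032 (n = 1000)
  importance: GCcds rank 1 (forest) / 1 (lasso); mean held-out Spearman 0.698
  coverage: median beta_start stab/ctrl/degr = -1.999 / -0.001 / 1.995
    rank-sum p (start): stabilized 4.81e-142, degraded 4.81e-142; 3'-control p: 1.00 / 1.00
  SLAM: stabilized recovery 0.889; labeled T>C fraction 0.147 (chase 0) -> 0.068 (chase 8)
  grid: 316 occupied cells, conservation TRUE
  checks: 10 of 10 passed
```

Reading the report: on 1000 simulated genes (30% translationally
suppressed, 15% the mirror class, per-assay effects up to 1.5 log2 units
scaled by GCcds), the TE test recovers 99.6% of planted classes with an
empirical FDR of 3.2%. Regressing measured Δ-TE on 90+ sequence features
within the suppressed class ranks GCcds first for both models. The
coverage stage plants a ±2 nt/h onset drift and the start-position slopes
recover medians of −2.0 / 0.0 / +2.0 nt/h for stabilized / control /
degraded transcripts (n = 250/1500/250), with the 3′-anchored control
showing no separation. The SLAM stage detects 89% of stabilized genes and
shows the expected drop in T>C-containing read fraction after an 8-h
chase (14.7% → 6.8% in labeled samples).

Individual stages are plain functions — `te_test()`,
`build_feature_table()`, `fit_forest_cv()`, `coverage_shift_analysis()`,
`stability_test()`, `bin_values()` — see the package help and the methods
vignette (`vignettes/gcstab-methods.Rmd`) for the models, parameter
meanings and design choices.

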