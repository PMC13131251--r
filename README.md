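# sleepmeta

Gene-wise random-effects meta-analysis of acute sleep-deprivation (SD)
effects on the rodent cortical transcriptome — and the scaffolding needed to
do it reproducibly: harmonization of per-contrast differential-expression
exports, REML heterogeneity estimation with moderator meta-regression
(SD duration, recovery sleep), Benjamini–Hochberg FDR control, preranked
gene-set enrichment with gene-permutation p-values, and validation of pooled
effects against an independently analysed two-group RNA-Seq count matrix via
direction/significance congruence statistics.

It is written for transcriptomics researchers who have per-study
differential-expression result tables (log2 fold changes with t-statistics)
rather than raw data, and who want calibrated pooled effects across small,
heterogeneous studies.

## The model

For gene *g* and contrast *i* (one SD-vs-control comparison), the observed
log2 fold change obeys

    y_gi = mu_g + u_gi + e_gi,   u_gi ~ N(0, tau2_g),  e_gi ~ N(0, v_gi)

with per-gene heterogeneity `tau2_g` estimated by REML and the pooled effect
by inverse-variance weighting, `w_i = 1/(v_gi + tau2_g)`. Genes must be
observed in at least 13 of 18 contrasts (generally `ceiling(0.722 * C)`).
An exploratory meta-regression adds centered SD duration and a
recovery-sleep factor, so the intercept stays interpretable as the SD effect
at the average duration without recovery sleep. Downstream, pooled effects
are ranked for weighted-KS preranked enrichment, and validated against a
count-based re-analysis (mean-count filter, TMM, voom weights,
empirical-Bayes moderated t via edgeR/limma).

## Worked example

The numbered scripts under `analysis/` run the whole chain on synthetic
multi-study data with known ground truth (2000 genes, 18 contrasts from 8
studies, 10% true DE, full recovery-sleep reversal), writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_meta_analysis.R
Rscript analysis/03_enrichment.R
Rscript analysis/04_validation.R
Rscript analysis/05_report.R
```

Output from a run:

```
harmonized 1991 genes passing the >= 13 of 18 contrast filter
top DEG G00177: pooled log2FC 0.148 [0.107, 0.189], FDR 2.9e-09 (forest table written)
sensitivity for true DE genes at FDR < 0.05: 0.57; null p < 0.05 rate: 0.066
directional ranking: 2 of 152 sets at FDR < 0.05; top: TRUE_SD_UP (ES 0.98, p 0.00038)
validation re-analysis: 2000 genes, 47 at FDR < 0.05
meta-analysis DEGs:        148
  represented in validation: 129
  same direction:            118 (91%)
  fully validated:           41 (32%)
OLS slope: 1.457 +/- 0.048; Spearman rho: 0.937
moderated-vs-plain effect slope over 129 DEGs: 1.48 +/- 0.01 (dilution if > 1)
DEGs with RS coefficient opposing the SD effect: 117 of 129 (91%)
two-sample t-test power for d = 0.5 at the pooled n = 293: 0.989
```

Reading this: the meta-analysis recovers more than half of the true DE
genes at FDR < 0.05 while the null false-positive rate stays near nominal;
the planted gene sets lead the enrichment ranking; most pooled DEGs
reproduce their direction in the independent count re-analysis; and because
the generator reverses SD effects under recovery sleep, the moderated model
(which controls for RS) estimates systematically larger SD effects than the
plain pooled model — the slope above 1 quantifies that dilution, and most
DEGs show an RS coefficient opposing their SD effect.

The same functions (`harmonize_contrasts()`, `run_meta()`,
`gsea_pvalues()`, `run_de_analysis()`, `congruence()`, `run_pipeline()`)
accept real per-contrast TSV exports, a contrast-metadata table, GMT files
and a count matrix; see the vignette in `vignettes/` for the model,
parameter and calibration details.

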