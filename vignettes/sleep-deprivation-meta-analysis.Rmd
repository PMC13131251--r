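---
title: "Gene-wise random-effects meta-analysis of sleep-deprivation transcriptome studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-wise random-effects meta-analysis of sleep-deprivation transcriptome studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Acute sleep deprivation (SD) in rodents — enforced wakefulness on the scale
of hours — perturbs cortical gene expression, but individual transcriptional
profiling studies are small (often fewer than ten animals per group) and
heterogeneous in platform, SD duration, and whether animals were allowed
recovery sleep (RS) before tissue collection. `sleepmeta` implements the
statistical machinery for pooling such studies at the gene level: it
harmonizes per-contrast differential-expression exports into a
gene-by-contrast effect matrix, fits a per-gene random-effects meta-analysis,
screens for functional enrichment, and quantifies congruence with an
independently analysed RNA-Seq dataset. A synthetic multi-study generator
with known ground truth makes the whole chain testable end to end.

# The model

For gene $g$, each contrast $i$ (one SD-vs-control comparison) contributes an
observed log2 fold change $y_{gi}$ with sampling variance $v_{gi}$. The
random-effects model is

$$y_{gi} = \mu_g + u_{gi} + \varepsilon_{gi}, \qquad
  u_{gi} \sim N(0, \tau^2_g), \quad \varepsilon_{gi} \sim N(0, v_{gi}),$$

where $\mu_g$ is the pooled SD effect and $\tau^2_g$ the between-contrast
heterogeneity. $\tau^2_g$ is estimated by restricted maximum likelihood
(Fisher scoring on the REML score $\tfrac12(y^\top P P y - \mathrm{tr}\,P)$
with projection at zero and a bounded golden-section fallback), and the
pooled effect is the inverse-variance weighted mean
$\hat\mu_g = \sum_i w_i y_{gi} / \sum_i w_i$ with
$w_i = 1/(v_{gi} + \hat\tau^2_g)$ and
$\mathrm{se}(\hat\mu_g) = (\sum_i w_i)^{-1/2}$.

Inference defaults to the Wald $z$ test ($p = 2\Phi(-|\hat\mu/\mathrm{se}|)$,
95% CI $\hat\mu \pm z_{0.975}\,\mathrm{se}$), matching the convention of the
standard meta-analysis tooling this field uses; a $t$ reference with $k-1$
degrees of freedom is available via `test = "t"` (see *Known limitations* —
the choice matters for FDR calibration at small $k$).

The exploratory moderated model replaces the intercept-only design with
$X = [1,\; \mathrm{dur}_i - \overline{\mathrm{dur}},\; \mathrm{RS}_i]$, where
duration is centered on the mean SD duration across **all** contrasts of the
design (not the per-gene available subset), so every gene's intercept is
interpretable as the SD effect at the average duration without recovery
sleep, and RS enters as a factor. Coefficients are GLS at the per-gene REML
$\hat\tau^2$, with per-coefficient Wald inference and per-coefficient BH FDR.

# Harmonization choices

The per-contrast exports carry probe-level log2FC, $t$, and $p$ but no
standard error, so probe SEs are recovered by the Wald identity
$\mathrm{se}_p = |\mathrm{log2FC}_p / t_p|$. Probes with $|t| < 10^{-8}$
carry no usable SE and are excluded from variance pooling (a gene with no
usable probe is dropped with a warning). Gene-level effects are the
arithmetic mean of probe log2FCs; the variance of that mean is pooled as
$(\sum_p \mathrm{se}_p^2)/P^2$ under probe independence, with
`probe_corr = "perfect"` (the mean of the probe variances) available because
the degree of within-platform probe correlation is unknowable from the
exports. Symbols match case-sensitively and exactly; duplicate symbol rows
within one contrast are collapsed by the same averaging rule, because the
meta-model requires one row per (gene, contrast). Genes must appear in at
least `ceiling(0.722 * C)` contrasts (13 of 18) to be analysed.

# The synthetic generator

`simulate_contrast_tables()` emulates the statistical structure the analysis
assumes, with defaults that mirror the emulated design: 18 contrasts from 8
studies, SD durations 3–12 h, RS (1–18 h) in 6 contrasts from 3 studies,
and plausible per-contrast animal counts. Per gene, a stratified 10% of
genes receive non-null effects $\mu_g \sim N(0, 0.1^2)$ (stratified rather
than Bernoulli so tests can assert exact counts), heterogeneity
$\tau^2_g \sim U(0, 0.005)$, and an RS coefficient $-\rho\,\mu_g$ with
reversal fraction $\rho = 1$ by default — RS hours are recorded in the
metadata but RS acts generatively as a factor, matching how the model codes
it. Sampling variance scales as $v_c = 0.005 \cdot 10/n_c$ (Wald-variance
behaviour of group-mean differences around a reference group size of 10);
these magnitudes put pooled SEs at $k = 18$ in the 0.01–0.09 range typical
of such meta-analyses. Missingness removes each (gene, contrast) cell
independently with probability 0.1, leaving most genes above the 13-of-18
coverage rule.

Probe rows are drawn as $x_p = \theta_{gc} + \eta_p$ with
$\eta_p \sim N(0, P\,v_{gc})$ and reported variance $P\,v_{gc}$, where
$\theta_{gc} = \mu_g + \beta^{RS}_g \mathbf{1}[RS_c] + u_{gc}$. The probe
average is then exactly $N(\theta_{gc}, v_{gc})$ for any probe count, so the
collapse step recovers a correctly calibrated effect/variance pair and the
single-probe case is just $P = 1$.

The validation generator draws negative-binomial counts (dispersion 0.05)
with the SD group's log2 mean shifted by each gene's $\mu_g$ and library
sizes log-uniform over $8\times10^6$–$4\times10^7$ so TMM normalization is
genuinely exercised; 43 samples per group mirror the scale of the emulated
validation dataset.

What the generator does **not** emulate: batch effects, platform-specific
probe biology, correlated genes, outlier samples, or the asymmetric,
dataset-specific missingness of real platforms. Passing tests therefore
demonstrate statistical correctness of the machinery under the stated model,
not robustness to those real-data pathologies.

# Enrichment

Preranked enrichment ranks converged genes by pooled log2FC (directional) or
its absolute value (non-directional); ties break by descending |statistic|
then symbol, so the order is total and runs are reproducible. The
enrichment score is the classic weighted Kolmogorov–Smirnov running sum
(weight exponent 1): members increment by $|r|/\sum_{S}|r|$, non-members
decrement by $1/(N - |S|)$, and the score is the extremal deviation with
sign retained (a magnitude tie between the positive and negative extremum
resolves positive). p-values come from gene permutation — `nperm` random
same-size sets — as the sign-conditional one-sided tail
$(1 + \#\{\text{same-sign } ES_{perm} \text{ at least as extreme}\})/(n_{side}+1)$,
the preranked-GSEA convention; this makes null p-values uniform and bounds
the minimum attainable p by the permutation count, which in turn floors the
BH-adjusted values: with $m$ sets, significance at FDR $q$ requires
$nperm \gtrsim m/q$. The simple permutation scheme estimates the same
quantity as adaptive multilevel methods, at desk scale; a normalized score
(ES over the mean same-sign permuted |ES|) is reported but secondary.

# Validation re-analysis

The count pipeline is deliberately the field-standard one, delegated to
edgeR/limma: strict mean-count filter (mean < 10 removed, exactly 10
retained), TMM factors at the canonical trims (30% on M, 5% on A,
variance weighting, geometric mean 1), log2-CPM with prior count 0.5 on
effective library sizes, voom precision weights (lowess span 0.5), a
treatment-only weighted fit, and empirical-Bayes variance moderation with
BH FDR. Condition is the only covariate by design. Congruence classifies
meta-analysis DEGs (FDR < q) as represented, same-direction, and fully
validated (same direction *and* validation FDR < q); the effect–effect
relationship is summarised by an unweighted OLS slope (validation on
meta-analysis by default — the orientation is configurable) and Spearman's
rho over the represented DEGs.

# Numerical choices and degenerate inputs

* REML: Fisher scoring from a DerSimonian–Laird start, tolerance $10^{-8}$
  on $\tau^2$, at most 100 iterations, projection at zero; on failure a
  bounded search on $[0, 100\max v]$. A gene is "stable" (converged) when
  either route converges and the resulting SE is finite; non-converged
  genes are reported but excluded from FDR, which operationalizes a
  stability notion the source analyses leave undefined.
* BH: step-up with explicit $\min$-cummin arithmetic, computed over
  non-missing p-values, with a one-ulp guard so `fdr >= p` holds exactly.
* p-values are floored at the smallest positive double so downstream log
  transforms never meet zero.
* Degenerate cases error early and informatively: zero-variance inputs,
  rank-deficient moderator designs (naming the collinear column), empty
  gene sets, sets spanning the whole universe, zero effective library
  sizes.
* Problem sizes in the tests and acceptance script — 800–2000 genes, 18
  contrasts, 20 FDR replicates, 400–10,000 permutations — are the package's
  chosen desk-scale versions of the full design; estimator behaviour at
  these sizes is representative because every per-gene fit is independent.

# Known limitations

* **Wald z vs FDR calibration.** With $k = 18$ contrasts the default Wald z
  test ignores the 17-df uncertainty in $\mathrm{se}(\hat\mu)$; its type-I
  error at 0.05 is mildly inflated (we measure ~0.05–0.07), but the
  inflation grows toward the tail, reaching roughly 2.7x at the p-values
  where BH draws its 5% line. Empirical FDR at $q = 0.05$ on stratified
  simulations is therefore ~0.12 rather than ≤ 0.05. This is a property of
  the z convention itself — the same choice made by the standard tooling —
  not of this implementation (which matches an independent reference to
  ~$10^{-9}$). `test = "t"` restores FDR control (~0.04 measured) at some
  cost in power, and is recommended when calibrated FDR matters more than
  convention.
* Gene-permutation enrichment p-values test a different null than
  sample-permutation GSEA and inherit inter-gene correlation optimism on
  real data; on the independence-simulated data here the two coincide.
* The harmonization stage trusts the exported t-statistics for SE recovery;
  platforms that moderate their t-statistics will yield slightly
  conservative sampling variances.
* No publication-bias diagnostics, alternative $\tau^2$ estimators, or
  network meta-analysis; single-species, single-tissue scope.
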