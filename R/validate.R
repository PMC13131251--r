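#' Remove genes with low mean raw counts
#'
#' Drops rows whose mean raw count is strictly below `threshold` (a gene
#' with mean exactly at the threshold is retained).
#'
#' @param counts nonnegative count matrix (genes x samples).
#' @param threshold mean-count cutoff (default 10).
#' @return filtered count matrix.
#' @export
filter_low_counts <- function(counts, threshold = 10) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  keep <- rowMeans(counts) >= threshold
  if (!any(keep)) stop("no genes pass the mean-count filter")
  message(sprintf("count filter: removed %d of %d genes (mean < %g)",
                  sum(!keep), length(keep), threshold))
  counts[keep, , drop = FALSE]
}

#' TMM between-sample normalization factors
#'
#' Trimmed mean of M-values with the canonical settings: reference column
#' chosen by 75th-percentile CPM closest to the mean, 30% two-sided trim on
#' log-ratios, 5% on average log abundance, inverse asymptotic-binomial
#' variance weighting, and factors rescaled to geometric mean 1. Computed
#' with `edgeR::calcNormFactors()`.
#'
#' @param counts filtered count matrix (>= 2 samples).
#' @return numeric vector of per-sample normalization factors.
#' @export
tmm_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  names(f) <- colnames(counts)
  f
}

#' Log2 counts per million with effective library sizes
#'
#' `log2((count + prior') / (lib * factor + 2 * prior') * 1e6)` where the
#' prior count is rescaled per sample in proportion to its effective library
#' size (the `edgeR::cpm()` convention; prior 0.5).
#'
#' @param counts count matrix.
#' @param factors TMM normalization factors (default 1).
#' @param prior pseudo-count (default 0.5).
#' @return log2-CPM matrix.
#' @export
log_cpm <- function(counts, factors = rep(1, ncol(counts)), prior = 0.5) {
  if (any(factors <= 0)) stop("normalization factors must be positive")
  lib <- colSums(counts) * factors
  if (any(lib <= 0)) stop("zero effective library size")
  edgeR::cpm(counts, lib.size = lib, log = TRUE, prior.count = prior)
}

#' Precision weights from the log-CPM mean-variance trend
#'
#' Per-gene linear fits on log-CPM, a lowess smooth (span 0.5) of
#' sqrt(residual SD) against mean log2 count, and per-observation predicted
#' square-root SDs interpolated at the fitted counts give weights
#' `predicted^-4` (the voom procedure; computed with `limma::voom()`).
#'
#' @param counts filtered count matrix.
#' @param factors TMM normalization factors.
#' @param design model matrix.
#' @param span lowess span.
#' @return matrix of observation weights, same dimensions as `counts`.
#' @export
voom_weights <- function(counts, factors = rep(1, ncol(counts)), design,
                         span = 0.5) {
  if (ncol(counts) - qr(design)$rank < 2)
    stop("fewer than 2 residual degrees of freedom")
  v <- limma::voom(counts, design, lib.size = colSums(counts) * factors,
                   span = span)
  unname(v$weights)
}

#' Precision-weighted differential expression with empirical-Bayes moderation
#'
#' Weighted least squares per gene on an intercept + condition design,
#' empirical-Bayes shrinkage of the residual variances toward a common prior
#' (method-of-moments on the log variances, as in `limma::eBayes()`),
#' moderated t-statistics on the augmented degrees of freedom, and BH FDR.
#'
#' @param logcpm log2-CPM matrix (genes x samples).
#' @param weights observation-weight matrix (same shape), or NULL.
#' @param condition factor/character per sample with exactly two levels;
#'   the second level (alphabetically, or of the factor) is the treatment.
#' @return data.frame: gene, log2fc (treatment - reference), ave_expr,
#'   t_mod, pval, fdr.
#' @export
fit_de <- function(logcpm, weights = NULL, condition) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2 || any(table(condition) < 2))
    stop("need exactly two conditions with >= 2 samples each")
  design <- stats::model.matrix(~condition)
  fit <- limma::lmFit(logcpm, design, weights = weights)
  fit <- limma::eBayes(fit)
  tab <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  data.frame(gene = rownames(logcpm), log2fc = tab$logFC,
             ave_expr = tab$AveExpr, t_mod = tab$t, pval = tab$P.Value,
             fdr = tab$adj.P.Val, stringsAsFactors = FALSE, row.names = NULL)
}

#' Full two-group RNA-Seq re-analysis
#'
#' Composes the validation pipeline: mean-count filter, TMM factors,
#' voom precision weights, log-CPM, weighted fit with empirical-Bayes
#' moderation, BH FDR.
#'
#' @param counts raw count matrix (genes x samples).
#' @param samples data.frame with `sample_id` and `condition` (levels CTRL
#'   and SD; SD is the treatment).
#' @param threshold mean-count filter cutoff.
#' @return `fit_de()` result table over the filtered genes.
#' @export
run_de_analysis <- function(counts, samples, threshold = 10) {
  stopifnot(identical(colnames(counts), samples$sample_id))
  counts <- filter_low_counts(counts, threshold)
  f <- tmm_factors(counts)
  condition <- factor(samples$condition, levels = c("CTRL", "SD"))
  design <- stats::model.matrix(~condition)
  w <- voom_weights(counts, f, design)
  lc <- log_cpm(counts, f)
  fit_de(lc, w, condition)
}

#' Congruence between meta-analysis and validation results
#'
#' Classifies the meta-analysis DEGs (FDR < q) by their behaviour in the
#' validation re-analysis: represented (present in the validation table),
#' same direction of effect, and fully validated (same direction and
#' validation FDR < q). Also reports the unweighted OLS slope of the
#' validation log2FC on the meta-analysis log2FC over the represented DEGs
#' (configurable orientation) and Spearman's rank correlation over the same
#' pairs.
#'
#' @param meta `meta_results` table ([run_meta()]).
#' @param de validation DE table ([fit_de()]/[run_de_analysis()]).
#' @param q FDR threshold (default 0.05).
#' @param orientation `"de_on_meta"` (default: meta effect on the x axis) or
#'   `"meta_on_de"`.
#' @return list of class `validation_summary`: n_degs, n_represented,
#'   n_same_direction, n_fully_validated, ols_slope, ols_slope_se,
#'   spearman_rho, plus the merged pair table.
#' @export
congruence <- function(meta, de, q = 0.05,
                       orientation = c("de_on_meta", "meta_on_de")) {
  orientation <- match.arg(orientation)
  if (!length(intersect(meta$gene, de$gene)))
    stop("meta-analysis and validation tables share no gene symbols")
  degs <- meta[!is.na(meta$fdr) & meta$fdr < q, ]
  pairs <- merge(degs[, c("gene", "log2fc")],
                 de[, c("gene", "log2fc", "fdr")],
                 by = "gene", suffixes = c("_meta", "_de"))
  if (!nrow(pairs)) stop("no meta-analysis DEGs represented in the validation table")
  same_dir <- sign(pairs$log2fc_meta) == sign(pairs$log2fc_de)
  fully <- same_dir & pairs$fdr < q
  fml <- if (orientation == "de_on_meta") log2fc_de ~ log2fc_meta
         else log2fc_meta ~ log2fc_de
  ols <- stats::lm(fml, data = pairs)
  slope <- summary(ols)$coefficients[2, 1:2]
  rho <- stats::cor(pairs$log2fc_meta, pairs$log2fc_de, method = "spearman")
  structure(list(n_degs = nrow(degs), n_represented = nrow(pairs),
                 n_same_direction = sum(same_dir),
                 n_fully_validated = sum(fully),
                 ols_slope = unname(slope[1]), ols_slope_se = unname(slope[2]),
                 spearman_rho = rho, pairs = pairs),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "meta-analysis DEGs:        %d\n",
    "  represented in validation: %d\n",
    "  same direction:            %d (%.0f%%)\n",
    "  fully validated:           %d (%.0f%%)\n",
    "OLS slope: %.3f +/- %.3f; Spearman rho: %.3f\n"),
    x$n_degs, x$n_represented,
    x$n_same_direction, 100 * x$n_same_direction / max(1, x$n_represented),
    x$n_fully_validated, 100 * x$n_fully_validated / max(1, x$n_degs),
    x$ols_slope, x$ols_slope_se, x$spearman_rho))
  invisible(x)
}
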