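#!/usr/bin/env Rscript
# Stage 4: independent validation. Re-analyse the two-group RNA-Seq count
# matrix (mean-count filter, TMM, voom precision weights, empirical-Bayes
# moderated t, BH FDR) and measure congruence of the meta-analysis DEGs:
# direction agreement, full validation (direction + FDR), OLS slope and
# Spearman correlation of the two effect-size estimates.

suppressMessages(library(sleepmeta))

out <- "results"
data_dir <- file.path(out, "data")

counts_df <- read.delim(file.path(data_dir, "validation_counts.tsv"),
                        check.names = FALSE)
counts <- as.matrix(counts_df[, -1])
rownames(counts) <- counts_df[[1]]
samples <- read.delim(file.path(data_dir, "validation_samples.tsv"))

de <- run_de_analysis(counts, samples)
sleepmeta:::write_tsv_num(de, file.path(out, "validation_de.tsv"))
cat(sprintf("validation re-analysis: %d genes, %d at FDR < 0.05\n",
            nrow(de), sum(de$fdr < 0.05)))

meta <- read.delim(file.path(out, "meta_intercept.tsv"))
cs <- congruence(meta, de, q = 0.05)
print(cs)
sleepmeta:::write_tsv_num(cs$pairs, file.path(out, "congruence_pairs.tsv"))
summary_df <- data.frame(
  n_degs = cs$n_degs, n_represented = cs$n_represented,
  n_same_direction = cs$n_same_direction,
  n_fully_validated = cs$n_fully_validated,
  ols_slope = cs$ols_slope, ols_slope_se = cs$ols_slope_se,
  spearman_rho = cs$spearman_rho)
sleepmeta:::write_tsv_num(summary_df, file.path(out, "congruence_summary.tsv"))
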