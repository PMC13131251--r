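#!/usr/bin/env Rscript
# Stage 2: harmonize the per-contrast tables and fit the per-gene
# random-effects meta-analysis (intercept-only main model and the
# exploratory moderated model with centered SD duration + RS factor).

suppressMessages(library(sleepmeta))

data_dir <- "results/data"
out <- "results"

metadata <- read.delim(file.path(data_dir, "contrast_metadata.tsv"))
paths <- setNames(file.path(data_dir, paste0(metadata$contrast_id, ".tsv")),
                  metadata$contrast_id)
mat <- harmonize_contrasts(paths, metadata)
write_effect_matrix(mat, file.path(out, "effects.tsv"),
                    file.path(out, "variances.tsv"))
cat(sprintf("harmonized %d genes passing the >= %d of %d contrast filter\n",
            length(mat$genes), mat$min_contrasts, nrow(metadata)))

plain <- run_meta(mat, "intercept")
moderated <- run_meta(mat, "moderated")
sleepmeta:::write_tsv_num(plain, file.path(out, "meta_intercept.tsv"))
sleepmeta:::write_tsv_num(moderated, file.path(out, "meta_moderated.tsv"))

# forest-plot export for the top DEG, mirroring the per-gene forest figures
top <- plain$gene[order(plain$pval)][1]
forest <- export_forest(top, plain, mat)
sleepmeta:::write_tsv_num(forest, file.path(out, "forest_top_gene.tsv"))
cat(sprintf("top DEG %s: pooled log2FC %.3f [%.3f, %.3f], FDR %.2g (forest table written)\n",
            top, forest$log2fc[forest$pooled], forest$ci_lb[forest$pooled],
            forest$ci_ub[forest$pooled], plain$fdr[plain$gene == top]))

# recovery against ground truth
truth <- read.delim(file.path(data_dir, "truth.tsv"))
truth <- truth[match(plain$gene, truth$gene), ]
cat(sprintf("sensitivity for true DE genes at FDR < 0.05: %.2f; null p < 0.05 rate: %.3f\n",
            mean(plain$fdr[truth$is_de] < 0.05, na.rm = TRUE),
            mean(plain$pval[!truth$is_de] < 0.05, na.rm = TRUE)))
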